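# Reference objects used across test files, built in code.

# labellable but non-spinal four-leaf network whose vertex 5 is an
# in-degree-4 hub (reconstructed from its cover)
hub_cover_text <- "{2,3};{1,5};{5};{4,7};{5,6};{5,7,9};{8,10}"

# degenerate spinal network on 4 leaves with a 5-set cover (the reticulation
# above the {1,4} cherry pair has two leaf children)
spinal5_cover_text <- "{1,4};{3,5};{2,6};{5,6,7};{7,8}"

shape_count_for <- function(class, n, k) {
  switch(class,
    STC = bessel_shapes(n, k),
    SSF = stirling2(n - 1 + k, n - 1),
    FTS = stirling1_unsigned(n - 1 + k, n - 1),
    BS  = count_bss_shapes(n, k),
    BSP = bsp_shapes(n, k))
}

network_count_for <- function(class, n, k) {
  switch(class,
    STC = count_stc(n, k), SSF = count_ssf(n, k), FTS = count_fts(n, k),
    BS = count_bs(n, k), BSP = count_bsp(n, k))
}

# all (n, k) pairs with n + 2k <= cap
small_nk_grid <- function(cap = 9) {
  out <- list()
  for (n in 1:cap) for (k in 0:((cap - n) %/% 2)) {
    out[[length(out) + 1L]] <- c(n = n, k = k)
  }
  out
}
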