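# Fixture builders shared across the suite. All landscapes are built in
# code; a patch with depth K/17 and area 1 ha has carrying capacity K at
# the default density.

patch_with_K <- function(K, id = 1, x = 0, y = 0, group = NULL) {
  df <- data.frame(id = id, area_ha = 1, depth_cm = K / 17, x_m = x, y_m = y)
  if (!is.null(group)) df$group <- group
  df
}

single_patch_landscape <- function(K = 50) landscape(patch_with_K(K))

two_patch_landscape <- function(K1 = 102, K2 = 102, d = 100) {
  landscape(rbind(patch_with_K(K1, id = 1, x = 0),
                  patch_with_K(K2, id = 2, x = d)))
}

# Small grouped landscape for scenario tests: two regions of three patches.
grouped_landscape <- function() {
  landscape(data.frame(
    id = 1:6,
    area_ha = c(0.5, 1, 0.25, 2, 0.75, 1.5),
    depth_cm = c(2, 4, 6, 3, 5, 1),
    x_m = c(0, 50, 100, 500, 550, 600),
    y_m = c(0, 40, 0, 0, 40, 0),
    group = rep(c("north", "south"), each = 3)
  ))
}

# Independently coded single-patch brute-force simulator: a plain loop over
# the ceiling-bounded Ricker-with-noise recursion and the N < 1 extinction
# rule. Returns one extinction year (tmax if the trial is censored).
brute_force_single_patch <- function(K, r_d, v_r, tmax, ceiling = 1) {
  n <- K
  if (n < 1) return(1L)
  for (t in 1:tmax) {
    n <- n * exp(r_d * (1 - n / K) + stats::rnorm(1, 0, sqrt(v_r)))
    n <- min(n, ceiling * K)
    if (n < 1) return(t)
  }
  tmax
}
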