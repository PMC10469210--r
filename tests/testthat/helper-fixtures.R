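# Shared fixtures, built once per test run (lazily) and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# coarse shell mesh used across geometry/darcy tests
fx_tiny_mesh <- function() fx_get("tiny_mesh", function() {
  generate_biventricle(target_edge = 12)
})

fx_tiny_regions <- function() fx_get("tiny_regions", function() {
  cs <- coronary_seeds(4)
  partition_regions(fx_tiny_mesh(), cs$seeds)
})

# complete tiny PH / AR runs (coarse mesh, 4 territories)
fx_tiny_ph <- function() fx_get("tiny_ph", function() {
  run_scenario(default_config(level = "tiny"), "ph")
})

fx_tiny_ar <- function() fx_get("tiny_ar", function() {
  run_scenario(default_config(level = "tiny"), "ar")
})

# study-size PH / AR runs used by the acceptance checks
fx_small_ph <- function() fx_get("small_ph", function() {
  run_scenario(default_config(level = "small"), "ph")
})

fx_small_ar <- function() fx_get("small_ar", function() {
  run_scenario(default_config(level = "small"), "ar")
})

# volume-weighted nodal mean of a field over a mesh
node_volume_weights <- function(mesh) {
  w <- numeric(nrow(mesh$vertices))
  for (a in 1:4) {
    s <- rowsum(mesh$cell_volumes / 4, mesh$tetrahedra[, a])
    idx <- as.integer(rownames(s))
    w[idx] <- w[idx] + s[, 1]
  }
  w
}
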