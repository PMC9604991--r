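# two coupled ensembles with unit fiber density at a given distance (mm)
pair_connectome <- function(d_mm = 17.1) {
  connectome(matrix(c(0, 1, 1, 0), 2, 2),
             matrix(c(0, d_mm, d_mm, 0), 2, 2))
}

# single isolated ensemble
single_connectome <- function() {
  connectome(matrix(0, 1, 1), matrix(0, 1, 1))
}

# short-horizon parameters for cheap integration tests
quick_params <- function(..., t_total = 5, t_transient = 1) {
  model_params(..., t_total = t_total, t_transient = t_transient)
}
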