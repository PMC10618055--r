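# shared in-code fixtures

# uniform-suitability landscape, one slice
flat_landscape <- function(value = 0.5, nx = 20, ny = 20, cell = 10,
                           bp_start = 1000, bp_end = 0, friction = NULL) {
  landscape(list(matrix(value, nx, ny)),
            data.frame(t_start_bp = bp_start, t_end_bp = bp_end),
            origin = c(0, 0), cell_size = cell, friction = friction)
}

# agents tibble builder
mk_agents <- function(x, y, population = 30, status = NULL, id = NULL) {
  n <- length(x)
  out <- tibble::tibble(id = if (is.null(id)) seq_len(n) else as.integer(id),
                        x = x, y = y,
                        population = rep_len(population, n))
  if (!is.null(status)) {
    S <- matrix(as.integer(status), nrow = n)
    colnames(S) <- paste0("s_", seq_len(ncol(S)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(S))
  }
  out
}

# analytic quadratic potential V = k |x|^2 / 2 (an OU benchmark)
quad_stub <- function(k = 1, sigma = 0) {
  potential_stub(grad = function(x, y) cbind(k * x, k * y), sigma = sigma)
}
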