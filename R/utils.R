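# Internal helpers: agents tibble <-> matrix state, growing accumulators.

# canonical agents tibble: id, x, y, population, s_1..s_c
agents_tbl <- function(ids, pos, D, S) {
  out <- tibble::tibble(id = as.integer(ids), x = pos[, 1], y = pos[, 2],
                        population = as.numeric(D))
  if (!is.null(S) && ncol(S) > 0) {
    Sm <- as.matrix(S)
    colnames(Sm) <- paste0("s_", seq_len(ncol(Sm)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(Sm))
  }
  out
}

status_cols <- function(agents) {
  grep("^s_[0-9]+$", names(agents), value = TRUE)
}

# extract matrices from an agents tibble
agents_mat <- function(agents) {
  sc <- status_cols(agents)
  list(ids = as.integer(agents$id),
       pos = cbind(agents$x, agents$y),
       D = as.numeric(agents$population),
       S = if (length(sc)) {
         m <- as.matrix(agents[sc]); storage.mode(m) <- "integer"; m
       } else matrix(integer(0), nrow(agents), 0))
}

check_agents <- function(agents) {
  need <- c("id", "x", "y")
  if (!all(need %in% names(agents)))
    stop("`agents` must have columns id, x, y", call. = FALSE)
  invisible(agents)
}

# growing numeric-matrix accumulator (amortised append)
grower <- function(ncol, colnames = NULL) {
  e <- new.env(parent = emptyenv())
  e$mat <- matrix(NA_real_, 256, ncol)
  e$n <- 0L
  e$colnames <- colnames
  e
}

grow_add <- function(g, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  k <- nrow(rows)
  if (k == 0) return(invisible(g))
  while (g$n + k > nrow(g$mat)) {
    g$mat <- rbind(g$mat, matrix(NA_real_, nrow(g$mat), ncol(g$mat)))
  }
  g$mat[g$n + seq_len(k), ] <- rows
  g$n <- g$n + k
  invisible(g)
}

grow_collect <- function(g) {
  m <- g$mat[seq_len(g$n), , drop = FALSE]
  colnames(m) <- g$colnames
  tibble::as_tibble(m)
}
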