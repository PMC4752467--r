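# Independent oracle: literal transcription of the seven SQFM formulas,
# kept separate from the package's implementation path.
sqfm_oracle <- function(x, y) {
  s_f <- sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
  r <- x / y
  s_f_prime <- sum(r) / (sqrt(length(x)) * sqrt(sum(r^2)))
  c_sim <- sum(x * y) / sum(y^2) * 100
  p_sim <- sum(x) / sum(y) * s_f * 100
  list(s_f = s_f, s_f_prime = s_f_prime, s_m = (s_f + s_f_prime) / 2,
       c = c_sim, p = p_sim, p_m = (c_sim + p_sim) / 2,
       alpha = abs(1 - p_sim / c_sim))
}

# Independent OLS oracle via the normal equations.
ols_oracle <- function(X, y) {
  A <- cbind(1, X)
  drop(solve(crossprod(A), crossprod(A, y)))
}

# Three batches x 5 peaks with identical retention grids.
make_simple_tables <- function(rts = c(3, 6, 9, 12, 15), shift = c(0, 0, 0)) {
  lapply(1:3, function(b) {
    peak_table(batch_id = paste0("B", b), wavelength = 260,
               retention_time = rts + shift[b],
               area = (1:5) * 10 * b)
  })
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

ishi_content_matrix <- function() {
  mc <- ishi_marker_contents()
  m <- as.matrix(mc[, c("UR", "AD", "CGA", "CFA", "CCA", "LGR", "LG")])
  rownames(m) <- mc$batch_id
  m
}
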