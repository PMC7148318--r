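# Small in-code fixtures shared across test files.

make_expr <- function(n_genes = 10, n_samples = 4, seed = 1, sd = 1,
                      mean = 8) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, mean, sd), nrow = n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_samples))))
    m
  })
}

write_expr_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Quadratic-time ssGSEA oracle: recomputes both cumulative distributions
# from scratch at every walk position. Independent of the package's
# implementation (shares only the definition).
ssgsea_oracle <- function(values, gene_set, alpha) {
  r <- rank(values, ties.method = "average")
  in_set <- names(values) %in% gene_set
  k <- sum(in_set)
  n <- length(values)
  ord <- order(r, decreasing = TRUE)
  denom_in <- sum(r[in_set]^alpha)
  es <- 0
  for (i in seq_len(n)) {
    visited <- ord[seq_len(i)]
    p_in <- sum(r[visited[in_set[visited]]]^alpha) / denom_in
    p_out <- sum(!in_set[visited]) / (n - k)
    es <- es + (p_in - p_out)
  }
  es
}

# Direct-formula moderated-t oracle: given prior (d0, s0_sq), applies the
# shrinkage and t formulas one gene at a time with scalar arithmetic.
moderated_t_oracle <- function(x, mutant, d0, s0_sq) {
  n1 <- sum(mutant); n2 <- sum(!mutant)
  df <- n1 + n2 - 2
  t(vapply(seq_len(nrow(x)), function(g) {
    a <- x[g, mutant]; b <- x[g, !mutant]
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    s2t <- if (is.infinite(d0)) s0_sq else (d0 * s0_sq + df * s2) / (d0 + df)
    tt <- (mean(a) - mean(b)) / sqrt(s2t * (1 / n1 + 1 / n2))
    c(t = tt, p = 2 * pt(-abs(tt), df = d0 + df))
  }, numeric(2)))
}
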