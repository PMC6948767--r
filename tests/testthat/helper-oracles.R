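# Independent oracles used across the suite. Each is a deliberately naive,
# formula-level implementation kept separate from the package's code paths.

# Pearson r from the raw definition, complete pairs only.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# One-way ANOVA from explicit sums of squares.
oracle_anova <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  groups <- split(y, g)
  ss_between <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, 0))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(groups) - 1L
  df2 <- length(y) - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(ss_between = ss_between, ss_within = ss_within, f = f,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       eta_squared = ss_between / (ss_between + ss_within))
}

# Upper hypergeometric tail P(X >= k) by exhaustive summation over the
# support, from binomial coefficients only (no d/p-hyper calls).
oracle_hyper_tail <- function(k, white, black, drawn) {
  kk <- seq(max(k, max(0, drawn - black)), min(white, drawn))
  if (!length(kk) || k > min(white, drawn)) return(0)
  sum(exp(lchoose(white, kk) + lchoose(black, drawn - kk) -
            lchoose(white + black, drawn)))
}

# Benjamini-Hochberg step-up applied literally: sort, p*(m/i), cumulative
# minimum from the largest p, map back.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch t statistic, Welch-Satterthwaite df and two-sided p, closed form.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p_two = 2 * stats::pt(-abs(t), df))
}

# All-pairs mutual ranks by explicit sorting on a small matrix.
oracle_mutual_rank <- function(mat, query) {
  genes <- rownames(mat)
  rank_in_list <- function(a, b) {
    others <- setdiff(genes, a)
    r <- vapply(others, function(g) oracle_pearson(mat[a, ], mat[g, ]), 0)
    ord <- others[order(-r, others)]
    match(b, ord)
  }
  others <- setdiff(genes, query)
  vapply(others, function(b) {
    sqrt(rank_in_list(query, b) * rank_in_list(b, query))
  }, 0)
}

# Small consistent dataset builder for toys.
toy_dataset <- function(values, conditions = NULL, id = "toy") {
  if (is.null(conditions)) conditions <- rep("c1", ncol(values))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_dataset(
    values,
    tibble::tibble(sample_id = colnames(values), condition = conditions),
    id
  )
}
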