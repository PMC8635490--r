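# Brute-force reference implementations, coded independently of the package
# internals, used to cross-check the vectorized paths.

# cell-by-cell cross-recurrence matrix
oracle_crp <- function(m1, m2, eps = 2, strict = TRUE) {
  n <- nrow(m1); m <- nrow(m2)
  out <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- 0
      for (k in seq_len(ncol(m1))) d <- d + abs(m1[i, k] - m2[j, k])
      hit <- if (strict) d < eps else d <= eps
      if (hit) out[i, j] <- 1L
    }
  }
  out
}

# walk every diagonal cell by cell, returning the length of each maximal run
oracle_diag_lines <- function(crp) {
  n <- nrow(crp); m <- ncol(crp)
  lens <- integer(0)
  for (k in seq(-(n - 1L), m - 1L)) {
    run <- 0L
    i <- max(1L, 1L - k)
    while (i <= n && i + k <= m) {
      if (crp[i, i + k] == 1L) {
        run <- run + 1L
      } else if (run > 0L) {
        lens <- c(lens, run); run <- 0L
      }
      i <- i + 1L
    }
    if (run > 0L) lens <- c(lens, run)
  }
  lens
}

# all five line measures straight from the run-length list
oracle_crqa <- function(crp, l_min = 8L) {
  lens <- oracle_diag_lines(crp)
  total <- sum(crp)
  if (total == 0) {
    return(list(crr = 0, l_mean = 0, l_max = 0,
                det_normalized = 0, det_as_printed = 0))
  }
  long <- lens[lens >= l_min]
  list(
    crr = 100 * total / (nrow(crp) * ncol(crp)),
    l_mean = if (length(long)) sum(long) / length(long) else 0,
    l_max = max(lens),
    det_normalized = sum(long) / sum(lens),
    det_as_printed = sum(long) / length(lens)
  )
}

# detection by enumerating every (start, length = min_run) pair
oracle_detect_run <- function(active, min_run = 3L) {
  n <- length(active)
  if (n < min_run) return(FALSE)
  for (start in seq_len(n - min_run + 1L)) {
    if (all(active[start:(start + min_run - 1L)])) return(TRUE)
  }
  FALSE
}

# balanced mixed-design ANOVA from cell/marginal means (textbook SS formulas)
oracle_mixed_anova <- function(tab) {
  y <- tab$y
  s <- factor(tab$s); g <- factor(tab$g); w <- factor(tab$w)
  grand <- mean(y)
  n_w <- nlevels(w)
  subj_means <- tapply(y, s, mean)
  subj_group <- tapply(as.character(g), s, function(x) x[1])
  ss_subj <- n_w * sum((subj_means - grand)^2)
  group_means <- tapply(y, g, mean)
  n_per_group <- table(subj_group)
  ss_group <- n_w * sum(n_per_group * (group_means[names(n_per_group)] -
                                         grand)^2)
  ss_subj_within <- ss_subj - ss_group
  n_subj <- nlevels(s)
  w_means <- tapply(y, w, mean)
  ss_w <- n_subj * sum((w_means - grand)^2)
  cell_means <- tapply(y, list(g, w), mean)
  ss_cells <- 0
  for (gi in levels(g)) {
    for (wi in levels(w)) {
      ss_cells <- ss_cells +
        n_per_group[[gi]] * (cell_means[gi, wi] - grand)^2
    }
  }
  ss_int <- ss_cells - ss_group - ss_w
  ss_total <- sum((y - grand)^2)
  ss_err_w <- ss_total - ss_subj - ss_w - ss_int
  n_g <- nlevels(g)
  df <- list(group = n_g - 1L, err_b = n_subj - n_g,
             w = n_w - 1L, int = (n_g - 1L) * (n_w - 1L),
             err_w = (n_subj - n_g) * (n_w - 1L))
  f_group <- (ss_group / df$group) / (ss_subj_within / df$err_b)
  f_w <- (ss_w / df$w) / (ss_err_w / df$err_w)
  f_int <- (ss_int / df$int) / (ss_err_w / df$err_w)
  list(
    between = list(F = f_group, df1 = df$group, df2 = df$err_b,
                   p = stats::pf(f_group, df$group, df$err_b,
                                 lower.tail = FALSE),
                   pes = ss_group / (ss_group + ss_subj_within)),
    within = list(F = f_w, df1 = df$w, df2 = df$err_w,
                  p = stats::pf(f_w, df$w, df$err_w, lower.tail = FALSE),
                  pes = ss_w / (ss_w + ss_err_w)),
    interaction = list(F = f_int, df1 = df$int, df2 = df$err_w,
                       p = stats::pf(f_int, df$int, df$err_w,
                                     lower.tail = FALSE),
                       pes = ss_int / (ss_int + ss_err_w))
  )
}

# closed-form standardized simple regression
oracle_regression <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(beta_std = r, t = t, df = n - 2L,
       p = 2 * stats::pt(-abs(t), n - 2), r_sq = r^2)
}

# random ordinal AU-like matrix (values 0..5)
random_ordinal_series <- function(n, d) {
  matrix(sample(0:5, n * d, replace = TRUE), n, d)
}
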