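# Independent brute-force reference implementations used to cross-check the
# package's estimators on small instances. These follow the definitions
# directly (nested enumeration, no shared code with the implementations).

sampen_brute <- function(x, M, r) {
  n <- length(x)
  nt <- n - M
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + M - 1)] - x[j:(j + M - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + M] - x[j + M]) <= r) A <- A + 1
      }
    }
  }
  list(A = A, B = B, sen = if (A > 0) -log(A / B) else Inf)
}

ami_brute <- function(x, lag, bins) {
  n <- length(x)
  breaks <- seq(min(x), max(x), length.out = bins + 1)
  b <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  bi <- b[1:(n - lag)]
  bj <- b[(1 + lag):n]
  mi <- 0
  np <- length(bi)
  for (u in 1:bins) {
    for (v in 1:bins) {
      pj <- sum(bi == u & bj == v) / np
      if (pj > 0) {
        mi <- mi + pj * log2(pj / ((sum(bi == u) / np) * (sum(bj == v) / np)))
      }
    }
  }
  mi
}

embed_brute <- function(x, m, tau) {
  nv <- length(x) - (m - 1) * tau
  mat <- matrix(NA_real_, nv, m)
  for (i in seq_len(nv)) for (k in seq_len(m)) mat[i, k] <- x[i + (k - 1) * tau]
  mat
}

fnn_brute <- function(x, tau, m_max, Rtol = 15, Atol = 2) {
  n <- length(x)
  sdx <- sd(x)
  eps <- 1e-10 * sdx
  out <- rep(NA_real_, m_max)
  for (m in seq_len(m_max)) {
    nv <- n - m * tau
    if (nv < 2) break
    emb <- embed_brute(x[seq_len(n)], m, tau)[seq_len(nv), , drop = FALSE]
    nfalse <- 0; total <- 0
    for (i in seq_len(nv)) {
      d <- sqrt(rowSums((emb - matrix(emb[i, ], nv, m, byrow = TRUE))^2))
      d[i] <- Inf
      j <- which.min(d)
      Rm <- d[j]
      extra <- abs(x[i + m * tau] - x[j + m * tau])
      Rm1 <- sqrt(Rm^2 + extra^2)
      ratio_false <- extra > eps && (Rm <= eps || (extra / Rm) > Rtol)
      if (ratio_false || (Rm1 / sdx) > Atol) nfalse <- nfalse + 1
      total <- total + 1
    }
    out[m] <- nfalse / total
  }
  out
}

rosenstein_brute <- function(x, m, tau, theiler, max_steps) {
  emb <- embed_brute(x, m, tau)
  nv <- nrow(emb)
  eps <- 1e-8 * sd(x)
  nbr <- integer(nv)
  for (i in seq_len(nv)) {
    d <- sqrt(rowSums((emb - matrix(emb[i, ], nv, m, byrow = TRUE))^2))
    d[abs(seq_len(nv) - i) <= theiler] <- Inf
    d[d <= eps] <- Inf
    nbr[i] <- which.min(d)
  }
  curve <- rep(NA_real_, max_steps + 1)
  for (k in 0:max_steps) {
    vals <- c()
    for (i in seq_len(nv)) {
      j <- nbr[i]
      if (i + k > nv || j + k > nv) next
      dk <- sqrt(sum((emb[i + k, ] - emb[j + k, ])^2))
      if (dk > 0) vals <- c(vals, log2(dk))
    }
    if (length(vals)) curve[k + 1] <- mean(vals)
  }
  curve
}

# Balanced-design projection oracle for the 2 x 2 x 2 mixed ANOVA: sums of
# squares from cell means, each within effect tested against its own
# interaction with subjects-within-groups.
anova_brute <- function(data) {
  d <- data
  d$subject <- as.character(d$subject)
  grand <- mean(d$value)
  s <- length(unique(d$subject)) / 2
  m_g <- tapply(d$value, d$group, mean)
  m_c <- tapply(d$value, d$condition, mean)
  m_v <- tapply(d$value, d$visit, mean)
  m_s <- tapply(d$value, d$subject, mean)
  subj_group <- tapply(d$group, d$subject, function(g) g[1])
  m_gc <- tapply(d$value, list(d$group, d$condition), mean)
  m_gv <- tapply(d$value, list(d$group, d$visit), mean)
  m_cv <- tapply(d$value, list(d$condition, d$visit), mean)
  m_gcv <- tapply(d$value, list(d$group, d$condition, d$visit), mean)
  m_sc <- tapply(d$value, list(d$subject, d$condition), mean)
  m_sv <- tapply(d$value, list(d$subject, d$visit), mean)
  groups <- names(m_g); conds <- names(m_c); visits <- names(m_v)
  subjects <- names(m_s)
  ss_group <- 4 * s * sum((m_g - grand)^2)
  ss_subj <- 4 * sum((m_s - m_g[subj_group[subjects]])^2)
  ss_cond <- 4 * s * sum((m_c - grand)^2)
  ss_visit <- 4 * s * sum((m_v - grand)^2)
  ss_gc <- 2 * s * sum((sweep(sweep(m_gc, 1, m_g), 2, m_c) + grand)^2)
  ss_gv <- 2 * s * sum((sweep(sweep(m_gv, 1, m_g), 2, m_v) + grand)^2)
  ss_cv <- 2 * s * sum((sweep(sweep(m_cv, 1, m_c), 2, m_v) + grand)^2)
  ss_gcv <- 0
  for (g in groups) for (cc in conds) for (v in visits) {
    eff <- m_gcv[g, cc, v] - m_gc[g, cc] - m_gv[g, v] - m_cv[cc, v] +
      m_g[g] + m_c[cc] + m_v[v] - grand
    ss_gcv <- ss_gcv + s * eff^2
  }
  ss_cs <- 0
  for (subj in subjects) for (cc in conds) {
    g <- subj_group[subj]
    eff <- m_sc[subj, cc] - m_s[subj] - m_gc[g, cc] + m_g[g]
    ss_cs <- ss_cs + 2 * eff^2
  }
  ss_vs <- 0
  for (subj in subjects) for (v in visits) {
    g <- subj_group[subj]
    eff <- m_sv[subj, v] - m_s[subj] - m_gv[g, v] + m_g[g]
    ss_vs <- ss_vs + 2 * eff^2
  }
  ss_total <- sum((d$value - grand)^2)
  ss_cvs <- ss_total - ss_group - ss_subj - ss_cond - ss_visit - ss_gc -
    ss_gv - ss_cv - ss_gcv - ss_cs - ss_vs
  df_err <- 2 * (s - 1)
  tibble::tibble(
    effect = c("group", "condition", "visit", "group x condition",
               "group x visit", "condition x visit", "group x condition x visit"),
    F = unname(c(ss_group / (ss_subj / df_err),
          ss_cond / (ss_cs / df_err),
          ss_visit / (ss_vs / df_err),
          ss_gc / (ss_cs / df_err),
          ss_gv / (ss_vs / df_err),
          ss_cv / (ss_cvs / df_err),
          ss_gcv / (ss_cvs / df_err)))
  )
}

bh_brute <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * alpha / m) k <- i
  sig <- rep(FALSE, m)
  if (k > 0) sig[ord[seq_len(k)]] <- TRUE
  sig
}

# Small balanced synthetic study table for ANOVA tests.
make_design <- function(n_per_group, seed = 1, cond_effect = 0, group_effect = 0,
                        visit_effect = 0, sd_subj = 1, sd_noise = 1) {
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(2 * n_per_group))
  d <- tidyr::expand_grid(subject = subjects, condition = c("firm", "foam"),
                          visit = 1:2)
  d$group <- ifelse(match(d$subject, subjects) <= n_per_group, "YO", "YN")
  ranef <- stats::setNames(rnorm(length(subjects), 0, sd_subj), subjects)
  d$value <- ranef[d$subject] + rnorm(nrow(d), 0, sd_noise) +
    ifelse(d$condition == "foam", cond_effect, 0) +
    ifelse(d$group == "YO", group_effect, 0) +
    ifelse(d$visit == 2, visit_effect, 0)
  d
}
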