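# Independent oracles used to check the analytical implementations.

# Probabilistic AUC by brute force over all (positive, negative) pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Two-sided Mann-Whitney p by full enumeration of label assignments.
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2,
              function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  if (u_obs > mu) {
    min(1, 2 * mean(us >= u_obs))
  } else if (u_obs < mu) {
    min(1, 2 * mean(us <= u_obs))
  } else 1
}

# Random small cohort in the standard schema, for property tests.
random_cohort <- function(n, p_ms = 0.25, p_censor = 0.4) {
  ms <- runif(n) < p_ms
  below <- runif(n) < p_censor
  csf <- ifelse(below, NA_real_,
                round(runif(n, 0.031, ifelse(ms, 1.5, 0.4)), 4))
  serum_alb <- round(runif(n, 3500, 5000), 1)
  q_alb <- runif(n, 0.002, 0.01)
  bands <- ifelse(ms & !below, rpois(n, 4) + 1L, rpois(n, 0.6))
  data.frame(
    id = sprintf("R%04d", seq_len(n)),
    diagnosis = ifelse(ms, "MS", "OTHER"),
    serum_kflc_mg_dl = round(runif(n, 0.5, 3), 3),
    csf_kflc_mg_dl = csf,
    csf_kflc_below_lod = below,
    serum_alb_mg_dl = serum_alb,
    csf_alb_mg_dl = q_alb * serum_alb,
    ocb_bands = as.integer(bands),
    stringsAsFactors = FALSE
  )
}
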