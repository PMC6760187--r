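# Independent brute-force oracles and small shared fixtures.

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
brute_rank_sum_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(length(x), n1)
  u_all <- apply(labelings, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  # two-sided: double the smaller tail, capped at 1
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Exact two-sided signed-rank p by enumeration of all sign assignments.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(as.matrix(signs), 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Single-fiber, fixed-latency response model for controlled planting.
fixed_mgf_responder <- function(tog = 1.3e-3, sdlog = 0.012) {
  response_model("EStim", region = "anterior",
                 tog_median = c(MGF = tog), tog_sdlog = c(MGF = sdlog),
                 success_prob = 1, ap_rate = 1, burst_adaptation = 1,
                 interval_growth = 1)
}

# Events table row in the detect_aps() schema.
make_event <- function(t_pos, t_neg = t_pos + 1.2e-3, amp = 1e-3) {
  k <- length(t_pos)
  data.frame(channel = rep("ch1", k), t_pos_s = t_pos, t_neg_s = t_neg,
             amplitude_v = rep(amp, length.out = k),
             lobe_separation_s = t_neg - t_pos,
             quality = rep(10, k), saturated = rep(FALSE, k),
             stringsAsFactors = FALSE)
}
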