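# Small constructors for hand-built statistic tables used across tests.

# Mimic cluster_probabilities() output from named cluster sizes.
make_prob_table <- function(sizes, mode = "selection") {
  out <- data.frame(tetramer = names(sizes),
                    n = as.integer(sizes),
                    p = as.numeric(sizes) / sum(sizes))
  attr(out, "total") <- sum(sizes)
  attr(out, "mode") <- mode
  class(out) <- c("probability_table", "data.frame")
  out
}

# Minimal rp_table for threshold / classification tests.
fake_rp_table <- function(tetramer, rp, kl_contrib = NULL, p_sel = NULL) {
  if (is.null(p_sel)) p_sel <- rep(1 / length(rp), length(rp))
  if (is.null(kl_contrib)) kl_contrib <- ifelse(p_sel > 0, p_sel * log2(rp), 0)
  out <- data.frame(tetramer = tetramer, rp = rp, p_sel = p_sel,
                    kl_contrib = kl_contrib,
                    rank = rank(-rp, ties.method = "min"))
  class(out) <- c("rp_table", "data.frame")
  out
}
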