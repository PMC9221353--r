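# Independent oracles and small fixtures used across the suite.

# Naive exact rank-sum null by recursive subset enumeration, written
# independently of the package's combn-based path. Returns the two-tailed
# and one-sided p for the observed rank-sum of group a.
naive_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  sums <- c()
  recurse <- function(start, chosen) {
    if (length(chosen) == na) {
      sums <<- c(sums, sum(r[chosen]))
      return(invisible())
    }
    if (start > length(pooled)) return(invisible())
    recurse(start + 1, c(chosen, start))
    # only continue skipping if enough elements remain
    if (length(pooled) - start >= na - length(chosen)) {
      recurse(start + 1, chosen)
    }
  }
  recurse(1, integer(0))
  eps <- 1e-9
  p_le <- mean(sums <= w_obs + eps)
  p_ge <- mean(sums >= w_obs - eps)
  list(p_two_tailed = min(1, 2 * min(p_le, p_ge)), p_greater = p_ge)
}

# A read tibble for one plate with specified control values and a common
# value in all compound wells.
make_plate_read <- function(layout, plate_id, condition, replicate_id = 1,
                            neg = rep(100, 8), pos = rep(1000, 8),
                            compound_value = 100) {
  lay <- plate_layout(layout, plate_id, condition)
  lay <- lay[lay$role != "empty", ]
  rlu <- numeric(nrow(lay))
  neg_wells <- sort(lay$well[lay$role == "negative_control"])
  pos_wells <- sort(lay$well[lay$role == "positive_control"])
  rlu[match(neg_wells, lay$well)] <- neg
  rlu[match(pos_wells, lay$well)] <- pos
  rlu[lay$role == "compound"] <- compound_value
  tibble::tibble(plate_id = plate_id, replicate_id = replicate_id,
                 condition = condition, well = lay$well, rlu = rlu)
}

small_layout <- function(n = 80) {
  build_screen_layout(sprintf("C%04d", seq_len(n)))
}
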