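# shared fixtures and independent brute-force oracles

tiny_table <- function() {
  asv_table(matrix(c(3L, 1L, 0L, 7L), 2, 2,
                   dimnames = list(c("A", "B"), c("S1", "S2"))))
}

random_table <- function(n_asv = 50, n_samp = 20, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_asv * n_samp, lambda), n_asv, n_samp,
              dimnames = list(sprintf("A%03d", seq_len(n_asv)),
                              sprintf("S%03d", seq_len(n_samp))))
  asv_table(m)
}

# a hand-built 3-dyad cohort table matching the worked set-arithmetic cases:
# dyad D1: mother {A,B,C}, T1 {B,C,D}, T2 {C,E}
demo_dyad_table <- function() {
  ids <- c("A", "B", "C", "D", "E")
  m <- cbind(M1 = c(5L, 5L, 5L, 0L, 0L),
             T1a = c(0L, 5L, 5L, 5L, 0L),
             T2a = c(0L, 0L, 5L, 0L, 5L))
  rownames(m) <- ids
  asv_table(m)
}

demo_dyad <- function() {
  list(dyad_id = "D1", group = "GDM", mother = "M1", t1 = "T1a", t2 = "T2a")
}

metadata_for <- function(dyad_ids, groups, with_t2 = TRUE) {
  rows <- lapply(seq_along(dyad_ids), function(i) {
    did <- dyad_ids[i]
    sid <- c(paste0(did, "M"), paste0(did, "T1"),
             if (with_t2) paste0(did, "T2"))
    data.frame(sample_id = sid, dyad_id = did, group = groups[i],
               role = c("mother", "infant", if (with_t2) "infant"),
               timepoint = c("antenatal", "T1", if (with_t2) "T2"),
               delivery_mode = "vaginal", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# brute-force transmission oracle: naive nested loops over ASV ids,
# independent of the package's set operations
oracle_transmission <- function(mother_counts, t1_counts, t2_counts, ids) {
  pres <- function(v) {
    out <- character(0)
    for (i in seq_along(ids)) if (v[i] > 0) out <- c(out, ids[i])
    out
  }
  mo <- pres(mother_counts); t1 <- pres(t1_counts); t2 <- pres(t2_counts)
  shared <- character(0); uniq <- character(0)
  for (a in t1) {
    hit <- FALSE
    for (b in mo) if (a == b) hit <- TRUE
    if (hit) shared <- c(shared, a) else uniq <- c(uniq, a)
  }
  transferred <- character(0)
  for (a in shared) {
    for (b in t2) if (a == b) transferred <- c(transferred, a)
  }
  list(
    n_t1 = length(t1), n_shared = length(shared), n_unique = length(uniq),
    n_transferred = length(transferred), n_t2 = length(t2),
    pct_shared = if (length(t1)) 100 * length(shared) / length(t1) else NA_real_,
    pct_retained = if (length(shared)) 100 * length(transferred) / length(shared) else NA_real_,
    pct_contribution = if (length(t2)) 100 * length(transferred) / length(t2) else NA_real_
  )
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

bray_hand <- function(a, b) 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
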