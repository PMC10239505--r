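# shared in-code fixtures: no data files, everything generated here

# minimal well-formed analyte table
make_small_table <- function(n_samples = 6, analytes = c("A", "B", "C")) {
  v <- matrix(seq_len(n_samples * length(analytes)) + 0.5,
              nrow = n_samples,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)), analytes))
  ann <- data.frame(analyte_id = analytes,
                    method = rep(c("LC", "FIA"), length.out = length(analytes)),
                    analyte_type = "measured", class = "test",
                    stringsAsFactors = FALSE)
  analyte_table(v, ann)
}

# metadata for a single-region, single-plate toy cohort
make_small_meta <- function(sample_ids, groups, region = "cortex",
                            plate = "P1") {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             subject_id = paste0("subj_", seq_len(n)),
             group = groups, region = region, plate_id = plate,
             sex = rep(c("M", "F"), length.out = n),
             age = 80 + seq_len(n) %% 5, education = 14, bmi = 25,
             hyperlipidemia = 0L, diabetes = 0L, renal_insufficiency = 0L,
             hypothyroidism = 0L, pmci = 3, storage = 8,
             stringsAsFactors = FALSE)
}

# independent oracle for the plate normalization equations: a literal,
# loop-based evaluation of the three defining steps, kept deliberately
# separate from the package implementation
oracle_plate_normalize <- function(x, group, plate) {
  r <- rep(NA_real_, length(x))
  for (g in unique(group)) {
    ix <- group == g
    r[ix] <- x[ix] / median(x[ix], na.rm = TRUE)
  }
  med_all <- median(r, na.rm = TRUE)
  q <- sapply(unique(plate), function(p) {
    median(r[plate == p], na.rm = TRUE) / med_all
  })
  y <- x / q[match(plate, unique(plate))]
  list(r = r, q = q, y = y)
}

# brute-force AUC: pairwise win probability with half-credit for ties
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# tiny synthetic cohort used across model tests
make_sim <- function(seed = 1, ...) {
  simulate_cohort(sim_config(n_analytes_lc = 4, n_analytes_fia = 4, ...),
                  seed = seed)
}
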