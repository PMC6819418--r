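# Builders for small hand-made cohorts used across test files.

# A cohort from explicit dose differences; covariates filled with valid
# placeholder anatomy unless supplied.
make_cohort <- function(dose_diff, bmi = NULL, a_heart = NULL,
                        d_median = NULL, ptv = NULL, label = NULL,
                        lad_prone = NULL) {
  n <- length(dose_diff)
  if (is.null(lad_prone)) lad_prone <- rep(10, n)
  df <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    bmi = if (is.null(bmi)) rep(25, n) + seq_len(n) * 0.1 else bmi,
    a_heart = if (is.null(a_heart)) rep(8, n) + seq_len(n) * 0.1 else a_heart,
    d_median = if (is.null(d_median)) rep(20, n) + seq_len(n) * 0.1 else d_median,
    ptv = if (is.null(ptv)) rep(800, n) + seq_len(n) else ptv,
    lad_prone = lad_prone,
    lad_supine = lad_prone + dose_diff
  )
  if (!is.null(label)) df$label <- label
  as_cohort(df)
}

# A cohort whose label column is arbitrary (e.g. simulated from a logistic
# model on extra columns); dose_diff is set consistent in sign with nothing
# in particular and extra predictor columns are attached.
make_label_cohort <- function(label, extra = NULL) {
  n <- length(label)
  co <- make_cohort(dose_diff = ifelse(label == 1, -1, 1), label = label)
  if (!is.null(extra)) for (nm in names(extra)) co[[nm]] <- extra[[nm]]
  class(co) <- c("position_cohort", "data.frame")
  co
}

# Brute-force O(n^2) tie-corrected AUC oracle.
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  total / (length(pos) * length(neg))
}

# Direct textbook net benefit at threshold probability pt.
nb_direct <- function(tp, fp, n, pt) tp / n - (pt / (1 - pt)) * fp / n
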