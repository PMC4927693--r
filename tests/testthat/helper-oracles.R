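# Independent brute-force oracles and fixture builders used across tests.

# adjacent-pair sum of resolution, written directly from the definition
brute_sum_rs <- function(df) {
  df <- df[order(df$tr_s), ]
  total <- 0
  if (nrow(df) >= 2) {
    for (i in seq_len(nrow(df) - 1)) {
      total <- total + 2 * abs(df$tr_s[i + 1] - df$tr_s[i]) /
        (df$width_s[i] + df$width_s[i + 1])
    }
  }
  total
}

# normalised resolution product by explicit loop
brute_nrp <- function(df) {
  df <- df[order(df$tr_s), ]
  rs <- numeric(0)
  for (i in seq_len(nrow(df) - 1)) {
    rs <- c(rs, 2 * abs(df$tr_s[i + 1] - df$tr_s[i]) /
              (df$width_s[i] + df$width_s[i + 1]))
  }
  if (length(rs) < 2) return(NA_real_)
  m <- mean(rs)
  out <- 1
  for (r in rs) out <- out * (r / m)
  out
}

# random peak table with distinct, well-separated retention times
random_peak_table <- function(n = NULL, condition_id = "rand") {
  if (is.null(n)) n <- sample(3:8, 1)
  gaps <- runif(n, 15, 80)
  tr <- 60 + cumsum(gaps)
  w <- runif(n, 4, 24)
  h <- runif(n, 100, 2000)
  peak_table(data.frame(
    analyte = sprintf("a%02d", seq_len(n)), tr_s = tr,
    area = h * w / 4 * sqrt(2 * pi), height = h, width_s = w,
    asym = runif(n, 1, 3), snr = runif(n, 5, 100),
    stringsAsFactors = FALSE), condition_id = condition_id)
}

# peak table with prescribed adjacent resolutions (all widths 10 s)
table_with_resolutions <- function(rs) {
  w <- 10
  tr <- 100 + c(0, cumsum(rs * w))
  peak_table(data.frame(
    analyte = sprintf("p%d", seq_along(tr)), tr_s = tr,
    area = 1, height = 1, width_s = w, stringsAsFactors = FALSE))
}

# anonymous synthetic panel of n compounds (generator supplies anchors)
make_panel <- function(n) {
  lapply(seq_len(n), function(i)
    compound_spec(sprintf("cmp%03d", i), "other", clogp = -2, mw = 150))
}

# tiny single-block design over valid factor levels
small_design <- function(additives = "water", columns = "Diol",
                         temperatures = 40) {
  screen_design(list(design_block(columns, additives, temperatures)))
}
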