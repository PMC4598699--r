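# small-population generator configs used across tests
tiny_config <- function(seed = 1, ...) {
  args <- list(n_herds = 6L, cows_per_herd = 8L, test_days_per_cow = 4L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Planted-offset world for the decomposition tests: per-milking contents are
# a cow-day base value plus/minus half a constant AM-PM offset `delta`
# (AM - PM), independent of milk yield, so the through-origin b-regressions
# identify the session means without dilution-induced weighting bias.
planted_split_data <- function(n_t = 2000, n_s = 2000, delta = 0.4,
                               noise = 0.1, seed = 1) {
  set.seed(seed)
  mk <- function(n) {
    base <- rnorm(n, 4.3, 0.4)
    list(milk_am = runif(n, 8, 16),
         milk_pm = runif(n, 9, 18),
         c_am = base + delta / 2 + rnorm(n, 0, noise),
         c_pm = base - delta / 2 + rnorm(n, 0, noise))
  }
  tt <- mk(n_t)
  ses <- rep(c("AM", "PM"), length.out = n_t)
  t_records <- data.frame(
    cow_id = sprintf("T%05d", seq_len(n_t)), herd_id = "H1",
    parity = "1", dim = 100L, month = 5L, test_day = 1L, session = ses,
    milk = ifelse(ses == "AM", tt$milk_am, tt$milk_pm),
    content_fat = ifelse(ses == "AM", tt$c_am, tt$c_pm),
    stringsAsFactors = FALSE)
  ss <- mk(n_s)
  s_records <- data.frame(
    cow_id = sprintf("S%05d", seq_len(n_s)), herd_id = "H1",
    parity = "1", dim = 100L, month = 5L,
    milk_am = ss$milk_am, milk_pm = ss$milk_pm,
    milk_daily = ss$milk_am + ss$milk_pm,
    content_5050_fat = 0.5 * ss$c_am + 0.5 * ss$c_pm,
    stringsAsFactors = FALSE)
  list(t_records = t_records, s_records = s_records,
       true_am = ss$c_am, true_pm = ss$c_pm)
}

# flat session frame with random class structure for model-fitting tests
random_session_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    cow_id = sprintf("C%04d", seq_len(n)), herd_id = "H1",
    dim = sample(5:365, n, replace = TRUE),
    parity = sample(c("1", "2", "3+"), n, replace = TRUE),
    month = sample(1:12, n, replace = TRUE),
    milk = runif(n, 8, 22),
    q_fat = rnorm(n, 4.3, 0.5),
    q_sfa = rnorm(n, 2.8, 0.35),
    stringsAsFactors = FALSE)
}

# through-origin slope standard error (independent closed form)
slope_se <- function(m, y, b) {
  sqrt(sum((y - b * m)^2) / (length(y) - 1)) / sqrt(sum(m^2))
}
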