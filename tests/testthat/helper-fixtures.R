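# deterministic 3-subject cohort with every table populated
toy_cohort <- function() {
  subjects <- data.frame(
    id = c("a", "b", "c"), sex = c("M", "F", "F"),
    age = c(40, 48, 60), height = c(180, 165, NA),
    weight = c(80, 62, 70), stringsAsFactors = FALSE)
  cord <- data.frame(
    id = rep(c("a", "b", "c"), each = 2),
    level = rep(c("C2-C3", "T9-T10"), 3),
    tca = c(85.2, 47.1, 78.4, 44.0, 74.9, 42.3),
    gm = c(20.5, 11.9, 19.2, 10.8, 18.1, 10.2),
    stringsAsFactors = FALSE)
  covariates <- data.frame(
    id = c("a", "b"),
    ticv = c(1550000, 1380000),
    ap_vertebra_diameter = c(16.2, 15.1),
    anterior_height = c(13.1, 12.4),
    posterior_height = c(12.7, 12.0),
    middle_vertebra_height = c(12.5, 11.9),
    stringsAsFactors = FALSE)
  cohort(subjects, cord, covariates)
}

# linear-model test data with known structure
lm_data <- function(n, seed = 1, sex_offset = 0, beta_x = 0, sd = 1) {
  set.seed(seed)
  sex <- rep(c("M", "F"), length.out = n)
  x <- rnorm(n)
  y <- 50 + sex_offset * (sex == "M") + beta_x * x + rnorm(n, 0, sd)
  data.frame(sex = sex, x = x, y = y)
}
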