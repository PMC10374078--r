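# Small shared helpers: time formatting and triangular sampling.

iso_format <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

iso_parse <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

weekday3 <- function(date) {
  # 0 = Sunday in POSIXlt
  c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[
    as.POSIXlt(as.Date(date))$wday + 1L]
}

# Symmetric triangular sampler around `mean` with half-width rel * mean;
# used for the ancillary stations whose true distributions are unknown.
rtriangular <- function(n, mean, rel = 0.5) {
  if (mean <= 0) return(rep(0, n))
  a <- mean * (1 - rel); b <- mean * (1 + rel)
  u <- stats::runif(n)
  ifelse(u < 0.5,
         a + sqrt(u * (b - a) * (mean - a)),
         b - sqrt((1 - u) * (b - a) * (b - mean)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
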