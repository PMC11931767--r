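# Internal helpers shared across modules.

# Round half away from zero, the convention used for the percentage tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic child seed derived from a root seed and a stream key, so that
# independent stages (network layout, hot-set choice, each year's events, each
# permutation trial) draw from non-interfering streams. Arithmetic stays below
# 2^31 and is exact in doubles.
child_seed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(as.character(key))) h <- (h * 31 + b) %% m
  as.integer(((seed %% m) * 48271 + h) %% m)
}

# Calendar year of a Date vector.
year_of <- function(date) as.integer(format(date, "%Y"))

# Fractional year: calendar year + (day of year - 1) / 365.25.
fractional_year <- function(date) {
  year_of(date) + (as.integer(format(date, "%j")) - 1) / 365.25
}

# Street-label normalization: lowercase, strip punctuation, collapse
# whitespace. "South St. & Main St." and "south st &  main st" agree.
normalize_label <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Canonical key for an unordered pair of street labels.
pair_key <- function(a, b) {
  a <- normalize_label(a)
  b <- normalize_label(b)
  ifelse(a <= b, paste(a, "&", b), paste(b, "&", a))
}

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

abort_stage <- function(stage, message) {
  stop(sprintf("[%s] %s", stage, message), call. = FALSE)
}
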