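# Shared internal helpers.

# Round half away from zero (printed epidemiological tables round 0.5 up,
# unlike base round()'s round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage to one decimal, the convention of the summary tables.
pct1 <- function(num, den) round_half_up(100 * num / den, 1)

stop_domain <- function(msg, ...) abort(msg, class = "pedsda_domain_error", ...)
stop_schema <- function(msg, ...) abort(msg, class = "pedsda_schema_error", ...)
stop_validation <- function(msg, ...) abort(msg, class = "pedsda_validation_error", ...)
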