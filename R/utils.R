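# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# population standard deviation (divide by n); a single observation has
# spread zero by convention so mu + 2*sigma stays defined
psd <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  sqrt(sum((x - mean(x))^2) / n)
}

sd_fun <- function(sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (sd_type == "population") psd else function(x) if (length(x) <= 1L) 0 else stats::sd(x)
}

# run expr with a private RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
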