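# Internal helpers shared across modules. Nothing here is protocol science;
# these exist so every stochastic entry point is reproducible from one root
# seed and so workload/lactate comparisons are immune to float dust.

`%||%` <- function(a, b) if (is.null(a)) b else a

MERSENNE31 <- 2147483647L

#' Derive a reproducible child seed from a root seed and labels
#'
#' Every source of randomness in the package (cohort generation, per-session
#' measurement noise, study replicates) draws its own stream seed with this
#' function, so re-running one session never perturbs another. Plain
#' polynomial string hash folded into the 31-bit range R accepts in
#' `set.seed()`.
#'
#' @param root integer root seed.
#' @param ... labels (coerced to character) naming the stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  lab <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  h <- abs(as.numeric(root)) %% MERSENNE31
  for (b in utf8ToInt(enc2utf8(lab))) h <- (h * 131 + b) %% MERSENNE31
  as.integer(h %% (MERSENNE31 - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so reproducible draws never perturb surrounding
#' randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Workload quantum for a modality
#'
#' All prescribed workloads are multiples of this quantum: 0.05 m/s on the
#' treadmill, 1 W on the cycle ergometer, so that the protocol increments
#' (0.1/0.15/0.3 m/s, 7/10/15 W) are representable exactly.
#'
#' @param modality `"running"` or `"cycling"`.
#' @return the quantum in workload units.
#' @export
workload_quantum <- function(modality) {
  switch(match.arg(modality, c("running", "cycling")),
         running = 0.05, cycling = 1)
}

# Snap a workload to the quantum grid (nearest multiple).
quantize_workload <- function(w, quantum) {
  round(round(w / quantum) * quantum, 10)
}

# Lactate deltas are compared after rounding to 0.01 mM (analyzer display
# resolution) so that strict ">" thresholds are not decided by float noise.
la_round <- function(x) round(x, 2)

exceeds <- function(delta, threshold) {
  isTRUE(delta > threshold + 1e-9)
}

# 31-bit content hash used to stamp outputs with the exact configuration.
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "")
  h <- 0
  for (b in utf8ToInt(enc2utf8(s))) h <- (h * 131 + b) %% MERSENNE31
  sprintf("%08x", as.integer(h))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("iltk_domain_error", "error")))
}
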