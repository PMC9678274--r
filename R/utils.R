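#' @keywords internal
"_PACKAGE"

# Enumerations shared across the package. Condition codes follow the two
# study designs: `control` (no algorithm decision, no mask), `no_mask` and
# `mask` (study 1), `alg65` and `alg95` (study 2: masked pairs presented with
# a 65% / 95% claimed algorithm accuracy rate).
fb_conditions <- c("control", "no_mask", "mask", "alg65", "alg95")
fb_labels     <- c("SAME", "DIFFERENT", "NONE")
fb_sources    <- c("GFMT", "MEDS", "CELEBRITY")

# Threshold grid of the 7-point rating scale: half-integers strictly between
# adjacent scale values -3..3.
fb_theta_grid <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)

fb_stop <- function(..., class = "facebias_error") {
  stop(errorCondition(sprintf(...), class = c(class, "facebias_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulation and bootstrap calls do not clobber the
#' session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and tags
#'
#' One master seed governs a whole analysis run; every bootstrap or
#' simulation stage derives its own stream from the master seed plus string
#' tags (condition, metric, ...), so results do not depend on the order in
#' which stages execute.
#'
#' @param master integer master seed.
#' @param ... character or numeric tags identifying the consumer.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "mask", "c")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  tag <- paste(vapply(list(...), paste, "", collapse = ","), collapse = "|")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer(h + 1)
}

# round-half-away-from-zero at 2 dp, the convention of the printed tables
round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100
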