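# Internal angle and RNG helpers. All user-facing angles are degrees; radians
# are used only transiently inside trigonometric calls.

.deg2rad <- function(x) x * pi / 180

.rad2deg <- function(x) x * 180 / pi

# Wrap to [0, 360)
.wrap360 <- function(x) x %% 360

# Wrap to (-180, 180]
.wrap180 <- function(x) {
  r <- x %% 360
  r[r > 180] <- r[r > 180] - 360
  r
}

.cosd <- function(x) cos(.deg2rad(x))
.sind <- function(x) sin(.deg2rad(x))

# Evaluate an expression under a temporary RNG state so that library calls are
# deterministic without clobbering the caller's random stream.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(expr)
}

# Deterministic per-(participant, stage) sub-seed, kept below 2^31 - 1.
.derivedSeed <- function(seed, participant, stage) {
  as.integer((as.double(seed) * 48271 + participant * 7919 + stage * 104729) %%
               2147483629)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# The eight signed offset bins of a generalization profile, in display order.
.offsetBins <- function() c(-135, -90, -45, 0, 45, 90, 135, 180)
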