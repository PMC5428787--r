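# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulation helpers do not perturb user code.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage child seed from a master seed; stays inside 32-bit range.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, localize = 211L, events = 307L,
    quantify = 401L, sholl = 503L, mask = 607L, render = 701L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be a single number, not NULL.", name))
  }
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

# Frame-to-time mapping used by every module: an event detected in frame k
# (0-based) is assigned the frame start time k * exposure_s.
frame_time <- function(frame, camera, start_time_s = 0) {
  start_time_s + frame * camera$exposure_s
}

# Column layout of localization tables (mirrors common SMLM table conventions).
loc_columns <- c("frame", "x_nm", "y_nm", "photons", "adc_sum",
                 "background", "sigma_nm", "loglik")

empty_localizations <- function() {
  tibble::tibble(
    frame = integer(), x_nm = double(), y_nm = double(), photons = double(),
    adc_sum = double(), background = double(), sigma_nm = double(),
    loglik = double()
  )
}

empty_events <- function() {
  tibble::tibble(
    event_id = integer(), x_nm = double(), y_nm = double(),
    t_start_s = double(), n_frames = integer(), total_photons = double(),
    member_ids = character()
  )
}
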