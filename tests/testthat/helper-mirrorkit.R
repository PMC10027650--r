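# shared fixtures: all synthetic, built in code at test time

# circular roll of a vector by k frames (mimic = stimulus shifted by k)
roll <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

# 30 s calibration stimulus yaw track at 120 fps
calibration_yaw <- function(duration_s = 30, fps = 120) {
  sample_states(make_calibration_script(), fps, as.integer(duration_s * fps))$ry
}

# independent brute-force lag estimator: loop over every admissible integer
# lag with plain cor(); reports the argmax reduced modulo the period
brute_force_shift <- function(ref, mim, s, L, period_f) {
  max_lag <- min(length(mim) - (s + L - 1L), 3L * period_f) - 1L
  cors <- vapply(0:max_lag, function(lag) {
    suppressWarnings(stats::cor(ref[s:(s + L - 1L)],
                                mim[(s + lag):(s + lag + L - 1L)]))
  }, numeric(1))
  cors[is.na(cors)] <- -Inf
  (which.max(cors) - 1L) %% period_f
}

random_face_state <- function() {
  face_state(
    pose = head_pose(tx = stats::runif(1, -50, 50), ty = stats::runif(1, -50, 50),
                     tz = stats::runif(1, -100, 100), rx = stats::runif(1, -30, 30),
                     ry = stats::runif(1, -45, 45), rz = stats::runif(1, -20, 20)),
    expression = expression_state(values = stats::setNames(
      stats::runif(length(AU_SET), 0, 5), AU_SET)),
    confidence = stats::runif(1)
  )
}

# a module type that always raises, for halt-and-flag tests
if (!"boom" %in% registered_module_types()) {
  register_module_type("boom", function(params) {
    list(process = function(msg, now) stop("boom module exploded"))
  })
}
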