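#' Questionnaire response matrices
#'
#' Visual-analogue ratings (0--100) arranged as a 3-d array
#' `[participant, item, condition]`, the container behind the weighted
#' sense-of-agency (SoA) scoring procedure. Conditions are labelled from
#' {B, P, E, PE}.
#'
#' @param values Numeric array `[participant, item, condition]` with
#'   dimnames, all values in [0, 100]; at least 3 participants and 2 items.
#' @return A `response_matrix`.
#' @export
response_matrix <- function(values) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (dim(values)[1] < 3) stop("need at least 3 participants")
  if (dim(values)[2] < 2) stop("need at least 2 items")
  if (any(values < 0 | values > 100)) stop("responses must lie in [0, 100]")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(
      paste0("p", seq_len(dim(values)[1])),
      paste0("item", seq_len(dim(values)[2])),
      c("B", "P", "E", "PE")[seq_len(dim(values)[3])]
    )
  structure(values, class = c("response_matrix", "array"))
}

#' Pool a response matrix over conditions
#'
#' Stacks the per-condition participant-by-item slices row-wise, yielding the
#' data points of all conditions for a condition-general analysis.
#'
#' @param responses A [response_matrix()].
#' @param condition Optional single condition label to select instead.
#' @return Numeric matrix (rows = participant-condition data points).
#' @export
pool_responses <- function(responses, condition = NULL) {
  conds <- dimnames(responses)[[3]]
  if (!is.null(condition)) {
    if (!condition %in% conds) stop("unknown condition: ", condition)
    return(responses[, , condition, drop = TRUE])
  }
  do.call(rbind, lapply(conds, function(cc) responses[, , cc, drop = TRUE]))
}

#' Unidimensional PCA loadings
#'
#' First-component loadings of the item correlation matrix: the leading
#' eigenvector scaled by the square root of its eigenvalue, i.e. each item's
#' correlation with the first principal component — a proxy for the latent
#' SoA variable. The sign is fixed so that the loadings sum to a positive
#' value. With `scope = "general"` the data points of all conditions are
#' pooled (condition-general loadings); with a condition label only that
#' condition's slice is used (condition-specific).
#'
#' @param responses A [response_matrix()].
#' @param scope `"general"` or one condition label.
#' @return A `loading_vector`: named numeric vector with a `scope` attribute.
#' @export
pca_loadings <- function(responses, scope = "general") {
  x <- if (identical(scope, "general")) pool_responses(responses)
       else pool_responses(responses, scope)
  if (nrow(x) < ncol(x) + 1)
    stop("need more data points than items for a stable component")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance item(s): ",
         paste(colnames(x)[vars == 0], collapse = ", "))
  e <- eigen(stats::cor(x), symmetric = TRUE)
  lambda <- e$values[1]
  v <- e$vectors[, 1]
  loadings <- v * sqrt(lambda)
  if (sum(loadings) < 0) loadings <- -loadings
  structure(stats::setNames(loadings, colnames(x)),
            scope = if (identical(scope, "general")) "condition-general"
                    else paste0("condition-specific:", scope),
            class = "loading_vector")
}

#' Tucker congruence coefficient
#'
#' The normalized inner product of two loading vectors,
#' `phi = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, in [-1, 1]. Scale-invariant
#' up to sign; used as a measurement-invariance index between
#' condition-general and condition-specific loadings. Conventional markers:
#' .85 fair, .95 good similarity.
#'
#' @param x,y Numeric loading vectors of equal length (>= 2), neither all
#'   zero.
#' @return Scalar `phi`.
#' @export
tucker_congruence <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("loading vectors must have equal length")
  if (length(x) < 2) stop("loading vectors must have length >= 2")
  if (all(x == 0) || all(y == 0)) stop("loading vectors must not be all zero")
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

#' Weighted sum scores
#'
#' The SoA score per participant and condition: each item's raw 0--100
#' response multiplied by its loading, then summed. With unit loadings this
#' is the plain item sum; the loadings weight each item by the magnitude of
#' its association with the latent variable.
#'
#' @param responses A [response_matrix()].
#' @param loadings A `loading_vector` (or plain numeric) of length = items.
#' @return Numeric matrix `[participant, condition]`.
#' @export
weighted_sum_score <- function(responses, loadings) {
  if (length(loadings) != dim(responses)[2])
    stop("loadings length must equal the number of items")
  conds <- dimnames(responses)[[3]]
  out <- sapply(conds, function(cc)
    as.numeric(responses[, , cc, drop = TRUE] %*% as.numeric(loadings)))
  rownames(out) <- dimnames(responses)[[1]]
  out
}

#' Measurement-invariance check by factor congruence
#'
#' Computes the Tucker congruence between the condition-general loading
#' vector and each condition-specific one. Report-only by default: the
#' conventional .85/.95 markers can be supplied as a benchmark, in which case
#' a pass flag per condition is added, but no hard thresholding is applied
#' otherwise.
#'
#' @param responses A [response_matrix()].
#' @param benchmark Optional scalar threshold (e.g. 0.85 or 0.95).
#' @return An `invariance_report`: `data.frame` with `condition`, `phi` and
#'   (if benchmarked) `pass`; the general loadings as an attribute.
#' @export
invariance_check <- function(responses, benchmark = NULL) {
  general <- pca_loadings(responses, "general")
  conds <- dimnames(responses)[[3]]
  phi <- vapply(conds, function(cc)
    tucker_congruence(general, pca_loadings(responses, cc)), numeric(1))
  report <- data.frame(condition = conds, phi = phi, row.names = NULL)
  if (!is.null(benchmark)) report$pass <- report$phi >= benchmark
  structure(report, class = c("invariance_report", "data.frame"),
            general_loadings = general)
}

#' Simulate questionnaire responses from a one-factor model
#'
#' Parameter-recovery generator for the scoring procedure:
#' `response[i, j, c] = clamp(mu_c + lambda_j * eta_ic + eps_ijc, 0, 100)`
#' with the latent score `eta ~ N(0, latent_sd)` per participant and
#' condition and item noise `eps ~ N(0, noise_sd)`, all independent.
#' Deterministic given `seed`.
#'
#' @param n Participants (>= 3).
#' @param loadings True item loadings `lambda`.
#' @param condition_means Named per-condition latent shift `mu_c` on the VAS
#'   scale; defaults mirror a baseline-lowest ordering B < P < E <= PE.
#' @param noise_sd Item noise SD (VAS units).
#' @param latent_sd SD of the latent score (VAS units).
#' @param seed Integer seed.
#' @return A [response_matrix()].
#' @export
synth_responses <- function(n = 200,
                            loadings = c(0.8, 0.75, 0.7, 0.65),
                            condition_means = c(B = 35, P = 50, E = 58, PE = 65),
                            noise_sd = 10, latent_sd = 15, seed = 1) {
  stopifnot(n >= 3)
  set.seed(as.integer(seed))
  k <- length(loadings)
  nc <- length(condition_means)
  vals <- array(NA_real_, dim = c(n, k, nc),
                dimnames = list(paste0("p", seq_len(n)),
                                paste0("item", seq_len(k)),
                                names(condition_means)))
  for (cc in seq_len(nc)) {
    eta <- stats::rnorm(n, 0, latent_sd)
    eps <- matrix(stats::rnorm(n * k, 0, noise_sd), n, k)
    vals[, , cc] <- pmin(100, pmax(0, condition_means[cc] +
                                     outer(eta, loadings) + eps))
  }
  response_matrix(vals)
}

#' Read and write long-format response CSVs
#'
#' Schema: `participant,condition,item,value`, one header line, VAS values in
#' [0, 100].
#'
#' @param responses A [response_matrix()].
#' @param path File path.
#' @return `read_responses()`: a `response_matrix`; `write_responses()`:
#'   `path` invisibly.
#' @export
write_responses <- function(responses, path) {
  dn <- dimnames(responses)
  long <- expand.grid(participant = dn[[1]], item = dn[[2]], condition = dn[[3]],
                      stringsAsFactors = FALSE)
  long$value <- as.numeric(responses)
  long <- long[c("participant", "condition", "item", "value")]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "item", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(errorCondition(
      paste0("responses file is missing column(s): ", paste(missing, collapse = ", ")),
      class = c("mirror_format_error", "error", "condition")))
  parts <- unique(df$participant)
  items <- unique(df$item)
  conds <- unique(df$condition)
  vals <- array(NA_real_, dim = c(length(parts), length(items), length(conds)),
                dimnames = list(parts, items, conds))
  vals[cbind(match(df$participant, parts), match(df$item, items),
             match(df$condition, conds))] <- df$value
  if (anyNA(vals)) stop("responses file does not cover the full design")
  response_matrix(vals)
}
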