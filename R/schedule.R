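#' Build counterbalanced induction schedules
#'
#' The validation design: every participant experiences four condition
#' blocks, the baseline B always first, followed by P, E and PE in an order
#' counterbalanced across participants (full permutation balancing: each of
#' the 6 orders of (P, E, PE) is used equally often when `n_participants` is
#' a multiple of 6, otherwise as evenly as possible, with a warning). Each
#' block is an induction phase of 30 s instruction, 180 s mirror exposure and
#' 30 s free interaction (240 s total). Every participant gets three distinct
#' avatars, randomly assigned, for the three post-baseline blocks; the
#' baseline avatar is drawn from the remaining pool. Five-minute breaks
#' between blocks are schedule metadata, not enforced.
#'
#' @param n_participants Number of participants (multiple of 6 for exact
#'   balance).
#' @param avatar_ids Pool of at least 4 avatar ids (at least 3 are needed for
#'   the distinct post-baseline assignment).
#' @param seed Integer seed for order and avatar assignment.
#' @param phase_s Phase durations, seconds: instruction, mirror, free.
#' @param break_s Break between blocks, seconds (metadata only).
#' @return An `induction_schedule`: `data.frame` with columns `participant`,
#'   `block`, `condition`, `avatar_id`, `phase`, `onset_s`, `duration_s`.
#' @export
build_schedule <- function(n_participants, avatar_ids = registered_avatars(),
                           seed = 1, phase_s = c(instruction = 30, mirror = 180,
                                                 free = 30),
                           break_s = 300) {
  stopifnot(n_participants >= 1)
  if (length(avatar_ids) < 3)
    config_error("need at least 3 avatar ids for distinct post-baseline assignment")
  if (n_participants %% 6 != 0)
    warning("n_participants is not a multiple of 6; ",
            "condition orders are balanced to within one participant")
  set.seed(as.integer(seed))
  perms <- list(c("P", "E", "PE"), c("P", "PE", "E"), c("E", "P", "PE"),
                c("E", "PE", "P"), c("PE", "P", "E"), c("PE", "E", "P"))
  # assign each of the 6 orders floor(n/6) or ceiling(n/6) times, shuffled
  order_idx <- rep(seq_along(perms), length.out = n_participants)
  order_idx <- sample(order_idx)
  block_len <- sum(phase_s)
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    conds <- c("B", perms[[order_idx[p]]])
    sync_avatars <- sample(avatar_ids, 3)
    b_avatar <- sample(avatar_ids, 1)
    avatars <- c(b_avatar, sync_avatars)
    onset <- 0
    prow <- vector("list", 4)
    for (b in seq_len(4)) {
      prow[[b]] <- data.frame(
        participant = p, block = b, condition = conds[b],
        avatar_id = avatars[b],
        phase = names(phase_s), onset_s = onset + cumsum(c(0, phase_s[-3])),
        duration_s = as.numeric(phase_s)
      )
      onset <- onset + block_len + break_s
    }
    rows[[p]] <- do.call(rbind, prow)
  }
  sched <- do.call(rbind, rows)
  rownames(sched) <- NULL
  structure(sched, class = c("induction_schedule", "data.frame"),
            block_s = block_len, break_s = break_s)
}

#' Write an induction schedule to CSV
#' @param schedule An `induction_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
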