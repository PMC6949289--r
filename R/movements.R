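# Movement-code semantics for the automated recording protocol.
#
# The protocol runs 22 numbered stages.  Stages 1-8 are single-DoF tasks with
# three sub-stages each (MVC in the two directions of the joint, then a
# 0.1 Hz sine-tracking task); 9-10 are circular 2D tracking (joysticks),
# 11-14 sine-tracked two-DoF "trumpet" tasks, and 15-22 synergistic grasps
# performed as 4 repetitions.  Cue-driven sub-stages (MVC and synergies)
# append a third digit to the code: x.y1 while the contraction cue is on,
# x.y0 during the rest/preparation period.  Tracking sub-stages keep the
# plain two-digit code for their whole duration.
#
# Codes are compared at 2-decimal precision throughout; internally they are
# held as integers scaled by 100 (0.01 steps are not exact binary floats).

code100 <- function(code) as.integer(round(code * 100))

#' Protocol movement table
#'
#' The list of protocol sub-stages with their numeric codes, matching the
#' `.Movements` element of a session file.  `kind` distinguishes cue-pulsed
#' MVC sub-stages, sine/circle tracking sub-stages and 4-repetition synergy
#' stages; `cue_digit` marks codes that gain a 0.01 increment while the
#' contraction cue is active.
#'
#' @return data frame with columns `code`, `description`, `kind`, `cue_digit`.
#' @examples
#' head(movement_table())
#' @export
movement_table <- function() {
  single <- list(
    c("Index finger", "flexion", "extension"),
    c("Middle finger", "flexion", "extension"),
    c("Ring finger", "flexion", "extension"),
    c("Little finger", "flexion", "extension"),
    c("Thumb", "flexion", "extension"),
    c("Thumb", "adduction", "abduction"),
    c("Wrist", "flexion", "extension"),
    c("Wrist", "supination", "pronation"))
  rows <- list()
  for (i in seq_along(single)) {
    s <- single[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      code = i + c(0.1, 0.2, 0.3),
      description = c(sprintf("%s: MVC %s", s[1], s[2]),
                      sprintf("%s: MVC %s", s[1], s[3]),
                      sprintf("%s: track sine cue", s[1])),
      kind = c("mvc", "mvc", "sine"),
      cue_digit = c(TRUE, TRUE, FALSE))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    code = c(9.1, 10.1),
    description = c("Thumb joystick: track circular cue",
                    "Wrist joystick: track circular cue"),
    kind = "circle", cue_digit = FALSE)
  trumpet <- c("index", "middle", "ring", "little")
  rows[[length(rows) + 1L]] <- data.frame(
    code = 11:14 + 0.1,
    description = sprintf("Touch %s finger with the thumb: track sine cue",
                          trumpet),
    kind = "sine", cue_digit = FALSE)
  synergy <- c("All fingers flexion (without thumb)", "All fingers extension",
               "Palmar grasp", "Pronation followed by palmar grasp",
               "Pointing: index extend, digits 3-5 flex", "3-digit pinch",
               "3-digit pinch with pronation",
               "Key grasp followed with pronation")
  rows[[length(rows) + 1L]] <- data.frame(
    code = 15:22 + 0.1,
    description = sprintf("%s: 4 repetitions", synergy),
    kind = "synergy", cue_digit = TRUE)
  out <- do.call(rbind, rows)
  out$code <- round(out$code, 2)
  rownames(out) <- NULL
  out
}

#' Decode a protocol movement code
#'
#' Splits a 2-decimal movement code into its base stage, sub-stage and cue
#' state.  For cue-pulsed sub-stages (MVC, synergies) the second decimal
#' distinguishes the active contraction cue (`x.y1`, `cue_active = "cue"`)
#' from the rest/preparation period (`x.y0`, `"rest"`); tracking sub-stages
#' carry no cue digit and report `cue_active = "na"`.
#'
#' @param code numeric movement code (e.g. `3.11`, `4.3`, `20.10`).
#' @return object of class `movement_code`: a list with `code`, `base`,
#'   `substage`, `cue_active`, `kind` and `description`.
#' @examples
#' decode_code(3.11)   # ring finger MVC flexion, cue on
#' decode_code(4.3)    # little finger sine tracking
#' @export
decode_code <- function(code) {
  stopifnot(is.numeric(code), length(code) == 1L)
  c100 <- code100(code)
  base <- c100 %/% 100L
  substage <- (c100 %% 100L) %/% 10L
  cue_digit <- c100 %% 10L
  tab <- movement_table()
  hit <- tab[code100(tab$code) == base * 100L + substage * 10L, ]
  if (nrow(hit) != 1L)
    stop("unknown movement code: ", format(code, nsmall = 2), call. = FALSE)
  if (!hit$cue_digit && cue_digit != 0L)
    stop("movement code ", format(code, nsmall = 2),
         " carries a cue digit but sub-stage ", hit$code,
         " is a tracking task", call. = FALSE)
  cue_active <- if (!hit$cue_digit) "na" else if (cue_digit == 1L) "cue"
                else if (cue_digit == 0L) "rest"
                else stop("cue digit must be 0 or 1 in code ", code,
                          call. = FALSE)
  structure(list(code = c100 / 100, base = base, substage = substage,
                 cue_active = cue_active, kind = hit$kind,
                 description = hit$description),
            class = "movement_code")
}

#' @rdname decode_code
#' @param base base stage number (1--22).
#' @param substage sub-stage digit.
#' @param cue_active `"cue"`, `"rest"` or `"na"`.
#' @return `encode_code()` returns the numeric 2-decimal code.
#' @export
encode_code <- function(base, substage, cue_active = "na") {
  stopifnot(cue_active %in% c("cue", "rest", "na"))
  code <- base + substage / 10 + if (cue_active == "cue") 0.01 else 0
  round(code, 2)
}

#' @export
print.movement_code <- function(x, ...) {
  state <- switch(x$cue_active, cue = " [cue on]", rest = " [rest]", na = "")
  cat(sprintf("Movement code %.2f: %s%s\n", x$code, x$description, state))
  invisible(x)
}

#' Locate the samples holding a movement code
#'
#' Finds the maximal runs of samples whose movement-code channel equals
#' `code` (compared at 2-decimal precision) and returns them as 1-based
#' inclusive `[start, end]` sample intervals, in order.
#'
#' @param rec a [session_record()], or a numeric movement-code stream.
#' @param code movement code to search for.
#' @return data frame with columns `start`, `end` (1-based, inclusive); zero
#'   rows when the code never occurs.
#' @examples
#' segment_by_code(c(0, 0, 4.3, 4.3, 4.3, 0), 4.3)
#' @export
segment_by_code <- function(rec, code) {
  stream <- if (inherits(rec, "session_record")) movement_stream(rec) else rec
  r <- rle(code100(stream) == code100(code))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
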