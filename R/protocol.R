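# The study protocol: 18 prescribed handling tasks (13 shaking movements, 5
# simulated daily-care activities), performed by each participant for 15 s
# while six body-worn IMUs record at 100 Hz.

#' The default handling-task protocol
#'
#' Returns the 18-task protocol: paired light/vigorous shaking tasks along
#' different axes, an aggressive shake while held by the legs and by the
#' shoulders, playful and aggressive arm swinging, a throw-and-catch, lift
#' and lower at two intensities, and five daily-care activities (diaper
#' change, leg bouncing, arm play, burping pats, cradling). Tasks
#' 2, 4, 6, 7, 8, 10 and 13 are high-risk; tasks 14-18 are daily care.
#'
#' @param n_participants Number of participants (default 8).
#' @param positions Sensor positions to record (default all six).
#' @param duration_s Task duration in seconds (default 15).
#' @return A list of class `protocol` with elements `tasks` (data.frame),
#'   `n_participants`, and `positions`.
#' @export
default_protocol <- function(n_participants = 8L,
                             positions = sensor_positions(),
                             duration_s = 15) {
  tasks <- data.frame(
    task_id = 1:18,
    name = c(
      "Gently shake up and down",
      "Vigorously shake up and down",
      "Lightly shake forward and back",
      "Aggressively shake forward and back",
      "Slowly shake side to side",
      "Quickly shake side to side",
      "Aggressively shake held by legs, head down",
      "Aggressively shake by the shoulders",
      "Swing arms slowly or playfully",
      "Swing arms aggressively",
      "Throw up in the air and catch playfully",
      "Lift and lower above head at normal speed",
      "Lift and lower above head aggressively",
      "Diaper-changing simulation",
      "Gentle leg bounce while seated",
      "Move arms as if gently playing",
      "Gentle back patting (burping)",
      "Two-arm cradling"
    ),
    risk = "no_risk",
    care_class = c(rep("shaking", 13L), rep("daily_care", 5L)),
    shake_axis = c("vertical", "vertical", "fore_aft", "fore_aft",
                   "lateral", "lateral", "mixed", "fore_aft",
                   "mixed", "mixed", "vertical", "vertical", "vertical",
                   NA, NA, NA, NA, NA),
    duration_s = duration_s,
    stringsAsFactors = FALSE
  )
  tasks$risk[c(2, 4, 6, 7, 8, 10, 13)] <- "high_risk"
  vapply(positions, assert_position, character(1))
  stopifnot(n_participants >= 1L)
  structure(list(tasks = tasks,
                 n_participants = as.integer(n_participants),
                 positions = positions),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("<protocol: %d tasks (%d high-risk, %d daily-care), %d participants, %d positions>\n",
              nrow(x$tasks), sum(x$tasks$risk == "high_risk"),
              sum(x$tasks$care_class == "daily_care"),
              x$n_participants, length(x$positions)))
  invisible(x)
}

# Ground-truth annotation label for a task: high-risk tasks are aggressive,
# no-risk shaking tasks are light, care tasks are daily_care.
task_label <- function(task) {
  if (task$risk == "high_risk") "aggressive"
  else if (task$care_class == "daily_care") "daily_care"
  else "light"
}
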