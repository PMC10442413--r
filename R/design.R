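#' Gross space per person on the single-file oval
#'
#' On a closed oval of given circumference walked single file by `n`
#' people, each person has `circumference / n` metres of path, reported to
#' 2 decimals (round half to even).
#'
#' @param circumference Oval circumference in m (the study oval is 14.97 m).
#' @param n Number of people on the oval (>= 1).
#' @return Gross space per person in m, rounded to 2 decimals.
#' @export
gross_space <- function(circumference = 14.97, n) {
  if (any(n < 1)) stop("n must be >= 1")
  stopifnot(circumference > 0)
  round(circumference / n, 2)
}

#' Net space per person after subtracting body depth
#'
#' Subtracts the average human body depth (0.288 m) from the *rounded*
#' gross space and rounds again (round, subtract, round). This convention
#' matters: for 24 people, 14.97/24 = 0.62375 rounds to 0.62 and
#' 0.62 - 0.288 = 0.332 gives 0.33, whereas subtracting before rounding
#' would give 0.34. Negative results are clipped to 0 with a warning.
#'
#' @param gross Rounded gross space in m (from [gross_space()]).
#' @param body_depth Average body depth in m.
#' @return Net space in m, rounded to 2 decimals, never negative.
#' @export
net_space <- function(gross, body_depth = 0.288) {
  stopifnot(all(gross >= 0))
  out <- round(gross - body_depth, 2)
  if (any(out < 0)) {
    warning("net space below 0 clipped to 0")
    out <- pmax(0, out)
  }
  out
}

#' Hall proxemic zone of an interpersonal distance
#'
#' Classifies a net distance into Hall's interpersonal-distance zones,
#' each split into a near and a far sub-zone (half-open upper bounds, m):
#' intimate near \[0, 0.15), intimate far \[0.15, 0.45), personal near
#' \[0.45, 0.75), personal far \[0.75, 1.2), social near \[1.2, 2.1),
#' social far \[2.1, 3.6), public >= 3.6. Violation of the inner zones by
#' strangers is associated with stress, which is why the zone a crowd
#' condition falls into is a useful design descriptor.
#'
#' @param net Net interpersonal distance(s) in m (>= 0).
#' @param thresholds Named numeric vector of zone lower bounds in m.
#' @return Factor of zone labels.
#' @export
hall_zone <- function(net, thresholds = c(intimate_near = 0, intimate_far = 0.15,
                                          personal_near = 0.45, personal_far = 0.75,
                                          social_near = 1.2, social_far = 2.1,
                                          public = 3.6)) {
  if (any(net < 0)) stop("net distance must be >= 0")
  lv <- names(thresholds)
  idx <- findInterval(net, thresholds)
  factor(lv[idx], levels = lv)
}

#' Floor-marker spacing for metronome pacing
#'
#' To impose a walking speed, the pacer covers the distance between two
#' floor markings in two metronome beats; the spacing is therefore
#' `speed * 2 * 60 / metronome` metres.
#'
#' @param speed Imposed walking speed in m/s.
#' @param metronome Metronome tempo in beats/min.
#' @return Marker spacing in m.
#' @export
marker_spacing <- function(speed, metronome) {
  if (any(metronome <= 0)) stop("metronome tempo must be positive")
  if (any(speed < 0)) stop("speed must be >= 0")
  speed * 2 * 60 / metronome
}

#' Occupancy conditions of the single-file oval experiment
#'
#' Reproduces the design table of the density study: for each occupant
#' count, the gross space per person on the 14.97 m oval, the net space
#' after subtracting 28.8 cm body depth (round-subtract-round convention,
#' see [net_space()]), and the Hall zone of the net spacing.
#'
#' @param n_persons Occupant counts.
#' @param circumference Oval circumference in m.
#' @param body_depth Average body depth in m.
#' @return Data frame with `n_persons`, `gross_space`, `net_space`,
#'   `hall_zone`.
#' @export
oval_conditions <- function(n_persons = c(4, 8, 16, 20, 24, 32, 36, 40),
                            circumference = 14.97, body_depth = 0.288) {
  g <- gross_space(circumference, n_persons)
  nt <- net_space(g, body_depth)
  data.frame(n_persons = n_persons, gross_space = g, net_space = nt,
             hall_zone = as.character(hall_zone(nt)))
}

#' Imposed-speed conditions of the pacing study
#'
#' @param speeds Imposed speeds in m/s.
#' @param duration_s Duration walked per speed in s.
#' @param headway Spacing between walkers in m.
#' @return Data frame with `label`, `speed`, `duration_s`, `headway`.
#' @export
speed_conditions <- function(speeds = c(1.41, 0.86, 0.31, 0.19),
                             duration_s = 180, headway = 1.5) {
  stopifnot(all(speeds >= 0))
  data.frame(label = formatC(speeds, format = "fg"), speed = speeds,
             duration_s = duration_s, headway = headway)
}
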