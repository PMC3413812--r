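#' Short-duration heating protocol
#'
#' Describes one balloon heating protocol: the balloon fluid temperature ramps
#' from body temperature to its maximum `t_peak` (the balloon maximum
#' temperature, reached just before the laser is switched off), then decays
#' exponentially toward the temperature of the continuously irrigated,
#' unheated coolant. Because the coolant is cooler than body temperature the
#' balloon temperature falls below 37 degrees C within 60 s of laser-off for
#' any peak up to 90 degrees C; the constructor enforces that bound.
#'
#' @param t_peak peak balloon temperature T_balloon, degrees C.
#' @param heating_time laser irradiation time, s (default 15).
#' @param baseline_temp body/bath temperature, degrees C (default 37).
#' @param cooling_time_constant exponential cooling time constant after
#'   laser-off, s (default 18).
#' @param coolant_temp asymptotic temperature of the irrigated coolant,
#'   degrees C (default 25; must be below `baseline_temp`).
#' @param ramp_time_constant time constant of the saturating-exponential
#'   heating ramp, s (default `heating_time / 3`).
#' @param balloon_pressure balloon pressure, MPa (metadata only, default 0.35).
#' @return an object of class `heating_protocol`.
#' @examples
#' p <- heating_protocol(75)
#' protocol_temperature(p, c(0, 15, 75))
#' @export
heating_protocol <- function(t_peak,
                             heating_time = 15,
                             baseline_temp = 37,
                             cooling_time_constant = 18,
                             coolant_temp = 25,
                             ramp_time_constant = heating_time / 3,
                             balloon_pressure = 0.35) {
  check_number(t_peak, "t_peak")
  check_number(heating_time, "heating_time", positive = TRUE)
  check_number(baseline_temp, "baseline_temp")
  check_number(cooling_time_constant, "cooling_time_constant", positive = TRUE)
  check_number(coolant_temp, "coolant_temp")
  check_number(ramp_time_constant, "ramp_time_constant", positive = TRUE)
  if (t_peak < baseline_temp) {
    abort_validation("`t_peak` must be >= `baseline_temp`: the balloon is heated, not chilled")
  }
  if (coolant_temp > baseline_temp) {
    abort_validation("`coolant_temp` must not exceed `baseline_temp`")
  }
  p <- structure(
    list(t_peak = t_peak, heating_time = heating_time,
         baseline_temp = baseline_temp,
         cooling_time_constant = cooling_time_constant,
         coolant_temp = coolant_temp,
         ramp_time_constant = ramp_time_constant,
         balloon_pressure = balloon_pressure),
    class = "heating_protocol")
  # the printed cooling claim: below body temperature within 60 s of laser-off
  if (t_peak <= 90) {
    t60 <- protocol_temperature(p, heating_time + 60)
    if (t60 > baseline_temp + 1e-9) {
      abort_validation(sprintf(
        "protocol violates the 60-s cooling bound: T(laser-off + 60 s) = %.2f degC > %.2f degC; shorten `cooling_time_constant` or lower `coolant_temp`",
        t60, baseline_temp))
    }
  }
  p
}

#' Evaluate a heating protocol's balloon temperature
#'
#' Closed-form balloon fluid temperature. During heating the temperature
#' follows a saturating exponential normalised to hit `t_peak` exactly at
#' laser-off (`heating_time`), so the maximum occurs just before the laser is
#' turned off; afterwards it decays exponentially toward `coolant_temp`.
#'
#' @param protocol a [heating_protocol()].
#' @param t time(s) since heating onset, s.
#' @return temperature(s), degrees C.
#' @export
protocol_temperature <- function(protocol, t) {
  stopifnot(inherits(protocol, "heating_protocol"))
  p <- protocol
  ramp <- function(tt) {
    frac <- (1 - exp(-tt / p$ramp_time_constant)) /
      (1 - exp(-p$heating_time / p$ramp_time_constant))
    p$baseline_temp + (p$t_peak - p$baseline_temp) * frac
  }
  cool <- function(tt) {
    p$coolant_temp + (p$t_peak - p$coolant_temp) *
      exp(-(tt - p$heating_time) / p$cooling_time_constant)
  }
  if (p$t_peak <= p$baseline_temp + 1e-12) {
    # zero forcing: no heating was performed, the balloon is never irrigated
    return(rep(p$baseline_temp, length(t)))
  }
  out <- numeric(length(t))
  heating <- t <= p$heating_time
  out[heating] <- ramp(t[heating])
  out[!heating] <- cool(t[!heating])
  out[t < 0] <- p$baseline_temp
  out
}

#' Generate a balloon temperature history
#'
#' Samples the protocol's closed-form temperature curve on a regular time
#' grid covering heating plus at least 90 s of cooling -- the window over
#' which the balloon is documented to fall back below body temperature.
#'
#' @param protocol a [heating_protocol()].
#' @param dt time step, s.
#' @param duration total duration, s; default `heating_time + 90`, and never
#'   less than that.
#' @return a data frame of class `temperature_history` with columns `time`
#'   (s) and `temp` (degrees C); the protocol is attached as an attribute.
#' @examples
#' h <- temperature_history(heating_protocol(75), dt = 0.5)
#' max(h$temp)                     # 75, at the end of heating
#' h$temp[h$time == 75]            # back below 37 degrees C
#' @export
temperature_history <- function(protocol, dt = 0.05,
                                duration = protocol$heating_time + 90) {
  stopifnot(inherits(protocol, "heating_protocol"))
  check_number(dt, "dt", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  if (duration < protocol$heating_time + 90) {
    abort_validation("`duration` must cover heating plus 90 s of cooling")
  }
  times <- seq(0, duration, by = dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  temps <- protocol_temperature(protocol, times)
  structure(data.frame(time = times, temp = temps),
            protocol = protocol,
            class = c("temperature_history", "data.frame"))
}

#' @export
print.temperature_history <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf(
    "Balloon temperature history: peak %.1f degC at %.1f s, %d samples over %.1f s\n",
    max(x$temp), x$time[which.max(x$temp)], nrow(x), max(x$time)))
  if (!is.null(p)) {
    cat(sprintf("  heating %g s (ramp tau %g s), cooling tau %g s toward %g degC\n",
                p$heating_time, p$ramp_time_constant,
                p$cooling_time_constant, p$coolant_temp))
  }
  invisible(x)
}

#' @export
plot.temperature_history <- function(x, ...) {
  graphics::plot(x$time, x$temp, type = "l", xlab = "time (s)",
                 ylab = "balloon temperature (degC)", ...)
  graphics::abline(h = attr(x, "protocol")$baseline_temp %||% 37, lty = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
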