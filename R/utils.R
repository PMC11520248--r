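# small internal helpers shared across modules

# wrap angles (degrees) into (-180, 180]
wrapAngle <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[!is.na(y) & y == -180] <- 180
  y
}

# numerically stable 1/(1+exp(z)) and exp(z)/(1+exp(z))
invOnePlusExp <- function(z) stats::plogis(-z)
expOverOnePlusExp <- function(z) stats::plogis(z)

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
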