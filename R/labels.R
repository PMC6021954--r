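#' Map 1-9 self-assessment ratings to a four-class emotion label
#'
#' Valence and arousal self-reports on the 1-9 Self-Assessment Manikin scale
#' are binarized: ratings 1-5 map to "low", 6-9 to "high". The joint label is
#' one of four classes indexed 0-3 in the fixed order LV-LA, LV-HA, HV-LA,
#' HV-HA (valence major, arousal minor).
#'
#' @param valence_raw integer rating in 1-9.
#' @param arousal_raw integer rating in 1-9.
#' @return An object of class `emotion_label`: list with `valence_raw`,
#'   `arousal_raw`, `valence_level`, `arousal_level` (`"low"`/`"high"`) and
#'   `class_index` (0-3).
#' @examples
#' emotion_label(7, 8)$class_index  # HV-HA -> 3
#' @export
emotion_label <- function(valence_raw, arousal_raw) {
  valence_raw <- as.integer(valence_raw)
  arousal_raw <- as.integer(arousal_raw)
  if (is.na(valence_raw) || valence_raw < 1L || valence_raw > 9L)
    stop_named("invalid_rating", "valence_raw must be an integer in 1..9")
  if (is.na(arousal_raw) || arousal_raw < 1L || arousal_raw > 9L)
    stop_named("invalid_rating", "arousal_raw must be an integer in 1..9")
  vlev <- if (valence_raw <= 5L) "low" else "high"
  alev <- if (arousal_raw <= 5L) "low" else "high"
  structure(list(
    valence_raw = valence_raw, arousal_raw = arousal_raw,
    valence_level = vlev, arousal_level = alev,
    class_index = class_index_from_levels(vlev, alev)
  ), class = "emotion_label")
}

#' @export
print.emotion_label <- function(x, ...) {
  cat(sprintf("<emotion_label> valence %d (%s), arousal %d (%s), class %d (%s)\n",
              x$valence_raw, x$valence_level, x$arousal_raw, x$arousal_level,
              x$class_index, class_names()[x$class_index + 1L]))
  invisible(x)
}

class_index_from_levels <- function(valence_level, arousal_level) {
  2L * (valence_level == "high") + 1L * (arousal_level == "high")
}

#' Names of the four valence/arousal classes in index order
#'
#' @return character vector `c("LV-LA", "LV-HA", "HV-LA", "HV-HA")`, i.e.
#'   classes 0-3.
#' @export
class_names <- function() c("LV-LA", "LV-HA", "HV-LA", "HV-HA")
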