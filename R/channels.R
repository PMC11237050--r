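#' Finger and channel conventions
#'
#' Fingers are labelled `D1` (thumb) through `D5` (little finger) and hands
#' `L`/`R`. Force channels are ordered `L_D1..L_D5, R_D1..R_D5` everywhere in
#' the package: in trace matrices, peak tables and on-disk CSV files.
#'
#' @format `finger_map` is a data frame with columns `digit` (`D1..D5`) and
#'   `name` (thumb, index, middle, ring, little).
#' @export
finger_map <- data.frame(
  digit = paste0("D", 1:5),
  name  = c("thumb", "index", "middle", "ring", "little"),
  stringsAsFactors = FALSE
)

FINGERS <- paste0("D", 1:5)
HANDS <- c("L", "R")

#' Channel labels in canonical order
#'
#' @return Character vector `L_D1..L_D5, R_D1..R_D5`.
#' @export
channel_names <- function() {
  c(paste0("L_", FINGERS), paste0("R_", FINGERS))
}

# Column index of a (hand, finger) pair in the 10-channel force matrix.
channel_index <- function(hand, finger) {
  hand <- match.arg(hand, HANDS)
  f <- match(finger, FINGERS)
  if (is.na(f)) stop("unknown finger label: ", finger)
  (hand == "R") * 5L + f
}

other_hand <- function(hand) if (hand == "L") "R" else "L"

#' Parse symptomatic-finger codes
#'
#' Symptom maps are stored as character vectors of codes like `"R-D3"`
#' (hand, dash, digit). Returns a data frame with columns `hand` and
#' `finger`; the empty vector parses to zero rows.
#'
#' @param codes character vector of `"<hand>-<digit>"` codes.
#' @return data frame with columns `hand`, `finger`.
#' @export
parse_symptom_map <- function(codes) {
  if (length(codes) == 0) {
    return(data.frame(hand = character(), finger = character(),
                      stringsAsFactors = FALSE))
  }
  ok <- grepl("^[LR]-D[1-5]$", codes)
  if (!all(ok)) {
    stop("malformed symptom code(s): ", paste(codes[!ok], collapse = ", "),
         " (expected e.g. \"R-D3\")")
  }
  data.frame(hand = substr(codes, 1, 1), finger = substr(codes, 3, 4),
             stringsAsFactors = FALSE)
}

# Fingers of `hand` flagged symptomatic in a symptom map.
symptomatic_fingers <- function(symptom_map, hand) {
  sm <- parse_symptom_map(symptom_map)
  unique(sm$finger[sm$hand == hand])
}
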