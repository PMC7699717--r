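#' Antimicrobial activity vocabulary
#'
#' The seven admissible activity codes: `G` (antibacterial), `Gpos`
#' (anti-Gram-positive), `Gneg` (anti-Gram-negative), `F` (antifungal),
#' `V` (antiviral), `P` (antiparasitic) and `C` (anticancer). `Gpos`/`Gneg`
#' are the ASCII on-disk forms of G+/G-; [activity_display()] converts to
#' the display forms. `G` is an independent annotation: no implication
#' from `Gpos`/`Gneg` to `G` is ever added automatically.
#'
#' @return Character vector of the seven canonical codes.
#' @export
#' @examples
#' activity_codes()
activity_codes <- function() {
  c("G", "Gpos", "Gneg", "F", "V", "P", "C")
}

#' Display form of activity codes
#'
#' @param codes character vector of canonical codes.
#' @return Character vector with `Gpos`/`Gneg` rendered as `G+`/`G-`.
#' @export
activity_display <- function(codes) {
  map <- c(G = "G", Gpos = "G+", Gneg = "G-", F = "F", V = "V", P = "P",
           C = "C")
  unname(map[match(codes, names(map))])
}

# Accepts canonical codes plus the display aliases G+/G-; anything else is
# rejected. Returns the canonical code.
normalize_activity <- function(code) {
  code <- trimws(code)
  alias <- c("G+" = "Gpos", "G-" = "Gneg")
  if (code %in% names(alias)) code <- unname(alias[code])
  if (!code %in% activity_codes()) {
    stop("unknown activity code: ", code, call. = FALSE)
  }
  code
}

#' Parse a serialized activity set
#'
#' Splits a `;`-separated activity string and validates every element
#' against the seven-code vocabulary. The display aliases `G+` and `G-`
#' are accepted and normalised to `Gpos`/`Gneg`.
#'
#' @param x a single string such as `"F;Gneg"`.
#' @param id peptide id used in error messages.
#' @return Character vector of unique canonical codes (input order kept).
#' @export
#' @examples
#' parse_activities("F;G-")
parse_activities <- function(x, id = "?") {
  if (is.na(x) || !nzchar(trimws(x))) {
    stop("empty activity set: ", id, call. = FALSE)
  }
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) stop("empty activity set: ", id, call. = FALSE)
  out <- vapply(parts, function(p) {
    tryCatch(normalize_activity(p),
             error = function(e) {
               stop("unknown activity code: ", p, " (peptide ", id, ")",
                    call. = FALSE)
             })
  }, character(1), USE.NAMES = FALSE)
  unique(out)
}
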