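#' @title ATC code parsing and hierarchy projection
#' @description
#' The Anatomical Therapeutic Chemical (ATC) classification assigns every drug
#' a code with five nested levels: the anatomical main group (1 letter), the
#' therapeutic subgroup (letter + 2 digits), the pharmacological subgroup
#' (+ 1 letter), the chemical subgroup (+ 1 letter) and the chemical substance
#' (+ 2 digits). A code's level is therefore determined by its length:
#' 1, 3, 4, 5 or 7 characters.
#'
#' Codes are represented as plain uppercase character vectors; [parseATC]
#' validates them and [atcLevel] infers the level from the length. No
#' dictionary lookup is performed: the syntactic rules above are the only
#' validation, with an optional user-supplied allow-list for strict mode.
#' @name atc
NULL

# code length at each ATC level
.ATC_LEVEL_NCHAR <- c(1L, 3L, 4L, 5L, 7L)

# the 14 anatomical main groups
.ATC_GROUPS <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")

#' Parse and validate ATC codes
#'
#' Validates one or more ATC codes against the syntactic rules of the
#' classification: length 1/3/4/5/7 characters (levels 1-5), position 1 a
#' letter from the 14 anatomical main groups, positions 2-3 digits,
#' positions 4-5 letters, positions 6-7 digits. Input is trimmed and
#' uppercased.
#'
#' @param text character vector of candidate codes (case-insensitive).
#' @param allow optional character vector of allowed codes (strict mode);
#'   when given, any code not in the list is rejected.
#' @return the validated codes as an uppercase character vector.
#' @examples
#' parseATC("J01CR02")
#' parseATC(c("j01cr02", "A02BC"))
#' atcLevel(parseATC("J01"))
#' @export
parseATC <- function(text, allow = NULL) {
  if (length(text) == 0L) return(character(0))
  code <- toupper(trimws(as.character(text)))
  bad <- is.na(code) | !nzchar(code)
  if (any(bad)) {
    stop("malformed ATC code: empty or missing at position(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  len <- nchar(code)
  if (any(!len %in% .ATC_LEVEL_NCHAR)) {
    off <- which(!len %in% .ATC_LEVEL_NCHAR)
    stop("malformed ATC code (length must be 1, 3, 4, 5 or 7): ",
         paste(unique(code[off]), collapse = ", "), call. = FALSE)
  }
  ok <- .atc_syntax_ok(code)
  if (any(!ok)) {
    stop("malformed ATC code (character class violation): ",
         paste(unique(code[!ok]), collapse = ", "), call. = FALSE)
  }
  grp <- substr(code, 1L, 1L)
  if (any(!grp %in% .ATC_GROUPS)) {
    stop("unknown ATC anatomical group: ",
         paste(unique(grp[!grp %in% .ATC_GROUPS]), collapse = ", "),
         " (must be one of ", paste(.ATC_GROUPS, collapse = ""), ")",
         call. = FALSE)
  }
  if (!is.null(allow)) {
    allow <- toupper(trimws(allow))
    if (any(!code %in% allow)) {
      stop("ATC code not in allow-list: ",
           paste(unique(code[!code %in% allow]), collapse = ", "),
           call. = FALSE)
    }
  }
  code
}

# vectorised character-class check, assuming length already in 1/3/4/5/7
.atc_syntax_ok <- function(code) {
  len <- nchar(code)
  ok <- grepl("^[A-Z]", code)
  has23 <- len >= 3L
  ok[has23] <- ok[has23] & grepl("^.[0-9]{2}", code[has23])
  has4 <- len >= 4L
  ok[has4] <- ok[has4] & grepl("^.{3}[A-Z]", code[has4])
  has5 <- len >= 5L
  ok[has5] <- ok[has5] & grepl("^.{4}[A-Z]", code[has5])
  has67 <- len == 7L
  ok[has67] <- ok[has67] & grepl("^.{5}[0-9]{2}$", code[has67])
  ok
}

#' Quietly test whether strings are valid ATC codes
#'
#' Vectorised predicate used by the record reader to count unparseable codes
#' without raising errors.
#'
#' @param text character vector.
#' @return logical vector, `TRUE` where [parseATC] would accept the string.
#' @export
isValidATC <- function(text) {
  code <- toupper(trimws(as.character(text)))
  len <- nchar(code)
  ok <- !is.na(code) & nzchar(code) & len %in% .ATC_LEVEL_NCHAR
  ok[ok] <- .atc_syntax_ok(code[ok]) & substr(code[ok], 1L, 1L) %in% .ATC_GROUPS
  ok
}

#' Infer the ATC level of codes
#'
#' @param code character vector of valid ATC codes.
#' @return integer vector of levels 1-5, inferred from code length.
#' @export
atcLevel <- function(code) {
  lev <- match(nchar(code), .ATC_LEVEL_NCHAR)
  if (anyNA(lev)) {
    stop("not an ATC code length: ",
         paste(unique(code[is.na(lev)]), collapse = ", "), call. = FALSE)
  }
  as.integer(lev)
}

#' Project ATC codes to a coarser hierarchy level
#'
#' Because the five ATC levels are nested by prefix, projecting a code upward
#' in the hierarchy is truncation to the target level's length. Projection to
#' the code's own level is the identity; projection to a finer level than the
#' code carries is impossible and raises an error.
#'
#' @param code character vector of valid ATC codes (validated on entry).
#' @param level target ATC level, integer 1-5, at or above the codes in the
#'   hierarchy (i.e. `level <= atcLevel(code)`).
#' @return character vector of codes at `level`.
#' @examples
#' projectToLevel("J01CR02", 2) # "J01"
#' projectToLevel("A02BC", 1)   # "A"
#' @export
projectToLevel <- function(code, level) {
  code <- parseATC(code)
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L || level > 5L) {
    stop("'level' must be a single integer in 1..5", call. = FALSE)
  }
  have <- atcLevel(code)
  if (any(have < level)) {
    stop("cannot refine: code(s) ",
         paste(unique(code[have < level]), collapse = ", "),
         " are above target level ", level,
         " (projection only goes upward in the hierarchy)", call. = FALSE)
  }
  substr(code, 1L, .ATC_LEVEL_NCHAR[level])
}
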