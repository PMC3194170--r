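# Double Metaphone phonetic encoder.
#
# Port of Lawrence Philips' Double Metaphone algorithm (2000). Every word is
# reduced to a primary and an alternate code of at most four symbols drawn
# from {A P K S T F H J L M N R X 0}; two words are considered
# phonetically equal when their codes coincide. The alternate code captures
# ambiguous pronunciations (e.g. Slavo-Germanic names); it equals the
# primary when no ambiguity arises.

DM_VOWELS <- c("A", "E", "I", "O", "U", "Y")

# state is mutated via environments to keep the port close to the original
# control flow; positions are 1-based throughout.

dm_char_at <- function(st, pos) {
  if (pos < 1 || pos > nchar(st)) return("")
  substr(st, pos, pos)
}

dm_string_at <- function(st, start, len, ...) {
  if (start < 1) return(FALSE)
  substr(st, start, start + len - 1L) %in% c(...)
}

dm_is_vowel <- function(st, pos) dm_char_at(st, pos) %in% DM_VOWELS

#' Double Metaphone codes for a single word
#'
#' Computes the primary and alternate Double Metaphone codes of one word.
#' Diacritics are folded to ASCII first; characters outside A-Z are dropped.
#' The empty string encodes to a pair of empty codes.
#'
#' @param word A length-1 character vector holding a single word (no
#'   internal whitespace; see [phonetic_encode()] for multi-word strings).
#' @return A character vector `c(primary = , alternate = )`. The alternate
#'   equals the primary unless an ambiguous rule fired.
#' @examples
#' double_metaphone("liver")
#' double_metaphone("Schmidt")
#' @export
double_metaphone <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  w <- toupper(iconv(word, from = "", to = "ASCII//TRANSLIT", sub = ""))
  w <- gsub("[^A-Z]", "", w)
  if (is.na(w) || !nzchar(w)) {
    return(c(primary = "", alternate = ""))
  }

  len <- nchar(w)
  last <- len
  st <- paste0(w, "     ")          # padding so lookahead never truncates
  slavo <- grepl("W|K|CZ|WITZ", w)

  pri <- ""
  alt <- ""
  add <- function(p, a = p) {
    pri <<- paste0(pri, p)
    alt <<- paste0(alt, a)
  }

  current <- 1L
  if (dm_string_at(st, 1L, 2L, "GN", "KN", "PN", "WR", "PS")) current <- 2L
  if (dm_char_at(st, 1L) == "X") {
    add("S")
    current <- 2L
  }

  while ((nchar(pri) < 4L || nchar(alt) < 4L) && current <= len) {
    ch <- dm_char_at(st, current)

    if (ch %in% DM_VOWELS) {
      if (current == 1L) add("A")
      current <- current + 1L

    } else if (ch == "B") {
      add("P")
      current <- current + if (dm_char_at(st, current + 1L) == "B") 2L else 1L

    } else if (ch == "C") {
      if (current > 2L && !dm_is_vowel(st, current - 2L) &&
          dm_string_at(st, current - 1L, 3L, "ACH") &&
          (dm_char_at(st, current + 2L) != "I" &&
           (dm_char_at(st, current + 2L) != "E" ||
            dm_string_at(st, current - 2L, 6L, "BACHER", "MACHER")))) {
        add("K"); current <- current + 2L
      } else if (current == 1L && dm_string_at(st, current, 6L, "CAESAR")) {
        add("S"); current <- current + 2L
      } else if (dm_string_at(st, current, 4L, "CHIA")) {
        add("K"); current <- current + 2L
      } else if (dm_string_at(st, current, 2L, "CH")) {
        if (current > 1L && dm_string_at(st, current, 4L, "CHAE")) {
          add("K", "X"); current <- current + 2L
        } else if (current == 1L &&
                   (dm_string_at(st, current + 1L, 5L, "HARAC", "HARIS") ||
                    dm_string_at(st, current + 1L, 3L, "HOR", "HYM", "HIA", "HEM")) &&
                   !dm_string_at(st, 1L, 5L, "CHORE")) {
          add("K"); current <- current + 2L
        } else if ((dm_string_at(st, 1L, 4L, "VAN ", "VON ") ||
                    dm_string_at(st, 1L, 3L, "SCH")) ||
                   dm_string_at(st, current - 2L, 6L, "ORCHES", "ARCHIT", "ORCHID") ||
                   dm_string_at(st, current + 2L, 1L, "T", "S") ||
                   ((dm_string_at(st, current - 1L, 1L, "A", "O", "U", "E") ||
                     current == 1L) &&
                    dm_string_at(st, current + 2L, 1L, "L", "R", "N", "M",
                                 "B", "H", "F", "V", "W", " "))) {
          add("K"); current <- current + 2L
        } else {
          if (current > 1L) {
            if (dm_string_at(st, 1L, 2L, "MC")) add("K") else add("X", "K")
          } else {
            add("X")
          }
          current <- current + 2L
        }
      } else if (dm_string_at(st, current, 2L, "CZ") &&
                 !dm_string_at(st, current - 2L, 4L, "WICZ")) {
        add("S", "X"); current <- current + 2L
      } else if (dm_string_at(st, current + 1L, 3L, "CIA")) {
        add("X"); current <- current + 3L
      } else if (dm_string_at(st, current, 2L, "CC") &&
                 !(current == 2L && dm_char_at(st, 1L) == "M")) {
        if (dm_string_at(st, current + 2L, 1L, "I", "E", "H") &&
            !dm_string_at(st, current + 2L, 2L, "HU")) {
          if ((current == 2L && dm_char_at(st, current - 1L) == "A") ||
              dm_string_at(st, current - 1L, 5L, "UCCEE", "UCCES")) {
            add("KS")
          } else {
            add("X")
          }
          current <- current + 3L
        } else {
          add("K"); current <- current + 2L
        }
      } else if (dm_string_at(st, current, 2L, "CK", "CG", "CQ")) {
        add("K"); current <- current + 2L
      } else if (dm_string_at(st, current, 2L, "CI", "CE", "CY")) {
        if (dm_string_at(st, current, 3L, "CIO", "CIE", "CIA")) {
          add("S", "X")
        } else {
          add("S")
        }
        current <- current + 2L
      } else {
        add("K")
        if (dm_string_at(st, current + 1L, 2L, " C", " Q", " G")) {
          current <- current + 3L
        } else if (dm_string_at(st, current + 1L, 1L, "C", "K", "Q") &&
                   !dm_string_at(st, current + 1L, 2L, "CE", "CI")) {
          current <- current + 2L
        } else {
          current <- current + 1L
        }
      }

    } else if (ch == "D") {
      if (dm_string_at(st, current, 2L, "DG")) {
        if (dm_string_at(st, current + 2L, 1L, "I", "E", "Y")) {
          add("J"); current <- current + 3L
        } else {
          add("TK"); current <- current + 2L
        }
      } else if (dm_string_at(st, current, 2L, "DT", "DD")) {
        add("T"); current <- current + 2L
      } else {
        add("T"); current <- current + 1L
      }

    } else if (ch == "F") {
      add("F")
      current <- current + if (dm_char_at(st, current + 1L) == "F") 2L else 1L

    } else if (ch == "G") {
      nxt <- dm_char_at(st, current + 1L)
      if (nxt == "H") {
        if (current > 1L && !dm_is_vowel(st, current - 1L)) {
          add("K"); current <- current + 2L
        } else if (current == 1L) {
          if (dm_char_at(st, current + 2L) == "I") add("J") else add("K")
          current <- current + 2L
        } else if ((current > 2L && dm_string_at(st, current - 2L, 1L, "B", "H", "D")) ||
                   (current > 3L && dm_string_at(st, current - 3L, 1L, "B", "H", "D")) ||
                   (current > 4L && dm_string_at(st, current - 4L, 1L, "B", "H"))) {
          current <- current + 2L
        } else {
          if (current > 3L && dm_char_at(st, current - 1L) == "U" &&
              dm_string_at(st, current - 3L, 1L, "C", "G", "L", "R", "T")) {
            add("F")
          } else if (current > 1L && dm_char_at(st, current - 1L) != "I") {
            add("K")
          }
          current <- current + 2L
        }
      } else if (nxt == "N") {
        if (current == 2L && dm_is_vowel(st, 1L) && !slavo) {
          add("KN", "N")
        } else if (!dm_string_at(st, current + 2L, 2L, "EY") &&
                   nxt != "Y" && !slavo) {
          add("N", "KN")
        } else {
          add("KN")
        }
        current <- current + 2L
      } else if (dm_string_at(st, current + 1L, 2L, "LI") && !slavo) {
        add("KL", "L"); current <- current + 2L
      } else if (current == 1L &&
                 (nxt == "Y" ||
                  dm_string_at(st, current + 1L, 2L, "ES", "EP", "EB", "EL",
                               "EY", "IB", "IL", "IN", "IE", "EI", "ER"))) {
        add("K", "J"); current <- current + 2L
      } else if ((dm_string_at(st, current + 1L, 2L, "ER") || nxt == "Y") &&
                 !dm_string_at(st, 1L, 6L, "DANGER", "RANGER", "MANGER") &&
                 !dm_string_at(st, current - 1L, 1L, "E", "I") &&
                 !dm_string_at(st, current - 1L, 3L, "RGY", "OGY")) {
        add("K", "J"); current <- current + 2L
      } else if (dm_string_at(st, current + 1L, 1L, "E", "I", "Y") ||
                 dm_string_at(st, current - 1L, 4L, "AGGI", "OGGI")) {
        if (dm_string_at(st, 1L, 4L, "VAN ", "VON ") ||
            dm_string_at(st, 1L, 3L, "SCH") ||
            dm_string_at(st, current + 1L, 2L, "ET")) {
          add("K")
        } else if (dm_string_at(st, current + 1L, 4L, "IER ")) {
          add("J")
        } else {
          add("J", "K")
        }
        current <- current + 2L
      } else {
        add("K")
        current <- current + if (nxt == "G") 2L else 1L
      }

    } else if (ch == "H") {
      if ((current == 1L || dm_is_vowel(st, current - 1L)) &&
          dm_is_vowel(st, current + 1L)) {
        add("H"); current <- current + 2L
      } else {
        current <- current + 1L
      }

    } else if (ch == "J") {
      if (dm_string_at(st, current, 4L, "JOSE") || dm_string_at(st, 1L, 4L, "SAN ")) {
        if ((current == 1L && dm_char_at(st, current + 4L) == " ") ||
            dm_string_at(st, 1L, 4L, "SAN ")) {
          add("H")
        } else {
          add("J", "H")
        }
        current <- current + 1L
      } else {
        if (current == 1L) {
          add("J", "A")
        } else if (dm_is_vowel(st, current - 1L) && !slavo &&
                   (dm_char_at(st, current + 1L) == "A" ||
                    dm_char_at(st, current + 1L) == "O")) {
          add("J", "H")
        } else if (current == last) {
          add("J", "")
        } else if (!dm_string_at(st, current + 1L, 1L, "L", "T", "K", "S",
                                 "N", "M", "B", "Z") &&
                   !dm_string_at(st, current - 1L, 1L, "S", "K", "L")) {
          add("J")
        }
        current <- current + if (dm_char_at(st, current + 1L) == "J") 2L else 1L
      }

    } else if (ch == "K") {
      add("K")
      current <- current + if (dm_char_at(st, current + 1L) == "K") 2L else 1L

    } else if (ch == "L") {
      if (dm_char_at(st, current + 1L) == "L") {
        if ((current == len - 2L &&
             dm_string_at(st, current - 1L, 4L, "ILLO", "ILLA", "ALLE")) ||
            ((dm_string_at(st, last - 1L, 2L, "AS", "OS") ||
              dm_string_at(st, last, 1L, "A", "O")) &&
             dm_string_at(st, current - 1L, 4L, "ALLE"))) {
          add("L", "")
          current <- current + 2L
        } else {
          add("L"); current <- current + 2L
        }
      } else {
        add("L"); current <- current + 1L
      }

    } else if (ch == "M") {
      add("M")
      if ((dm_string_at(st, current - 1L, 3L, "UMB") &&
           (current + 1L == last || dm_string_at(st, current + 2L, 2L, "ER"))) ||
          dm_char_at(st, current + 1L) == "M") {
        current <- current + 2L
      } else {
        current <- current + 1L
      }

    } else if (ch == "N") {
      add("N")
      current <- current + if (dm_char_at(st, current + 1L) == "N") 2L else 1L

    } else if (ch == "P") {
      if (dm_char_at(st, current + 1L) == "H") {
        add("F"); current <- current + 2L
      } else {
        add("P")
        current <- current +
          if (dm_char_at(st, current + 1L) %in% c("P", "B")) 2L else 1L
      }

    } else if (ch == "Q") {
      add("K")
      current <- current + if (dm_char_at(st, current + 1L) == "Q") 2L else 1L

    } else if (ch == "R") {
      if (current == last && !slavo &&
          dm_string_at(st, current - 2L, 2L, "IE") &&
          !dm_string_at(st, current - 4L, 2L, "ME", "MA")) {
        add("", "R")
      } else {
        add("R")
      }
      current <- current + if (dm_char_at(st, current + 1L) == "R") 2L else 1L

    } else if (ch == "S") {
      if (dm_string_at(st, current - 1L, 3L, "ISL", "YSL")) {
        current <- current + 1L
      } else if (current == 1L && dm_string_at(st, current, 5L, "SUGAR")) {
        add("X", "S"); current <- current + 1L
      } else if (dm_string_at(st, current, 2L, "SH")) {
        if (dm_string_at(st, current + 1L, 4L, "HEIM", "HOEK", "HOLM", "HOLZ")) {
          add("S")
        } else {
          add("X")
        }
        current <- current + 2L
      } else if (dm_string_at(st, current, 3L, "SIO", "SIA") ||
                 dm_string_at(st, current, 4L, "SIAN")) {
        if (!slavo) add("S", "X") else add("S")
        current <- current + 3L
      } else if ((current == 1L &&
                  dm_string_at(st, current + 1L, 1L, "M", "N", "L", "W")) ||
                 dm_string_at(st, current + 1L, 1L, "Z")) {
        add("S", "X")
        current <- current +
          if (dm_string_at(st, current + 1L, 1L, "Z")) 2L else 1L
      } else if (dm_string_at(st, current, 2L, "SC")) {
        if (dm_char_at(st, current + 2L) == "H") {
          if (dm_string_at(st, current + 3L, 2L, "OO", "ER", "EN", "UY",
                           "ED", "EM")) {
            if (dm_string_at(st, current + 3L, 2L, "ER", "EN")) {
              add("X", "SK")
            } else {
              add("SK")
            }
            current <- current + 3L
          } else {
            if (current == 1L && !dm_is_vowel(st, 4L) &&
                dm_char_at(st, 4L) != "W") {
              add("X", "S")
            } else {
              add("X")
            }
            current <- current + 3L
          }
        } else if (dm_string_at(st, current + 2L, 1L, "I", "E", "Y")) {
          add("S"); current <- current + 3L
        } else {
          add("SK"); current <- current + 3L
        }
      } else {
        if (current == last && dm_string_at(st, current - 2L, 2L, "AI", "OI")) {
          add("", "S")
        } else {
          add("S")
        }
        current <- current +
          if (dm_char_at(st, current + 1L) %in% c("S", "Z")) 2L else 1L
      }

    } else if (ch == "T") {
      if (dm_string_at(st, current, 4L, "TION")) {
        add("X"); current <- current + 3L
      } else if (dm_string_at(st, current, 3L, "TIA", "TCH")) {
        add("X"); current <- current + 3L
      } else if (dm_string_at(st, current, 2L, "TH") ||
                 dm_string_at(st, current, 3L, "TTH")) {
        if (dm_string_at(st, current + 2L, 2L, "OM", "AM") ||
            dm_string_at(st, 1L, 4L, "VAN ", "VON ") ||
            dm_string_at(st, 1L, 3L, "SCH")) {
          add("T")
        } else {
          add("0", "T")
        }
        current <- current + 2L
      } else {
        add("T")
        current <- current +
          if (dm_char_at(st, current + 1L) %in% c("T", "D")) 2L else 1L
      }

    } else if (ch == "V") {
      add("F")
      current <- current + if (dm_char_at(st, current + 1L) == "V") 2L else 1L

    } else if (ch == "W") {
      if (dm_string_at(st, current, 2L, "WR")) {
        add("R"); current <- current + 2L
      } else if (current == 1L &&
                 (dm_is_vowel(st, current + 1L) ||
                  dm_string_at(st, current, 2L, "WH"))) {
        if (dm_is_vowel(st, current + 1L)) add("A", "F") else add("A")
        current <- current + 1L
      } else if ((current == last && dm_is_vowel(st, current - 1L)) ||
                 dm_string_at(st, current - 1L, 5L, "EWSKI", "EWSKY",
                              "OWSKI", "OWSKY") ||
                 dm_string_at(st, 1L, 3L, "SCH")) {
        add("", "F"); current <- current + 1L
      } else if (dm_string_at(st, current, 4L, "WICZ", "WITZ")) {
        add("TS", "FX"); current <- current + 4L
      } else {
        current <- current + 1L
      }

    } else if (ch == "X") {
      if (!(current == last &&
            (dm_string_at(st, current - 3L, 3L, "IAU", "EAU") ||
             dm_string_at(st, current - 2L, 2L, "AU", "OU")))) {
        add("KS")
      }
      current <- current +
        if (dm_char_at(st, current + 1L) %in% c("C", "X")) 2L else 1L

    } else if (ch == "Z") {
      if (dm_char_at(st, current + 1L) == "H") {
        add("J"); current <- current + 2L
      } else {
        if (dm_string_at(st, current + 1L, 2L, "ZO", "ZI", "ZA") ||
            (slavo && current > 1L && dm_char_at(st, current - 1L) != "T")) {
          add("S", "TS")
        } else {
          add("S")
        }
        current <- current + if (dm_char_at(st, current + 1L) == "Z") 2L else 1L
      }

    } else {
      current <- current + 1L
    }
  }

  c(primary = substr(pri, 1L, 4L), alternate = substr(alt, 1L, 4L))
}

#' Phonetic encoding of a (possibly multi-word) term
#'
#' Encodes each whitespace-separated word with [double_metaphone()] and
#' joins the per-word codes with `sep`, preserving word order. Encoding
#' word-by-word keeps word boundaries: whole-string encoding would let
#' unrelated multi-word terms collide.
#'
#' @param text Character vector of terms.
#' @param sep Separator placed between per-word codes (default `" "`).
#' @return A data frame with columns `text`, `primary`, `alternate`
#'   (one row per input term).
#' @examples
#' phonetic_encode(c("bone marrow", "kidney"))
#' @export
phonetic_encode <- function(text, sep = " ") {
  stopifnot(is.character(text))
  enc1 <- function(x) {
    words <- strsplit(trimws(x), "\\s+")[[1]]
    words <- words[nzchar(words)]
    if (length(words) == 0L) return(c(primary = "", alternate = ""))
    codes <- vapply(words, double_metaphone, character(2L))
    c(primary = paste(codes["primary", ], collapse = sep),
      alternate = paste(codes["alternate", ], collapse = sep))
  }
  codes <- vapply(text, enc1, character(2L))
  data.frame(text = text,
             primary = unname(codes["primary", ]),
             alternate = unname(codes["alternate", ]),
             stringsAsFactors = FALSE, row.names = NULL)
}
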