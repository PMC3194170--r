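# fixtures are built in code at test time; nothing binary ships with the
# package

obo_fixture_path <- function() {
  path <- file.path(tempdir(), "anatomap-fixture.obo")
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: T:001",
    "name: liver",
    'synonym: "hepatic tissue" EXACT []',
    "",
    "[Term]",
    "id: T:002",
    "name: kidney",
    'synonym: "renal organ" []',
    "",
    "[Term]",
    "id: T:003",
    "name: Ureter",
    "",
    "[Term]",
    "id: T:004",
    "name: ureter",
    "",
    "[Term]",
    "id: T:005",
    "name: old liver",
    "is_obsolete: true",
    ""
  ), path)
  path
}

toy_ontology <- function() {
  as_ontology(
    tibble::tibble(
      id = c("T:001", "T:002", "T:003", "T:004", "T:005", "T:006"),
      label = c("liver", "kidney", "bone marrow", "femur",
                "pyloric antrum", "left ventricle of heart"),
      obsolete = FALSE),
    tibble::tibble(id = "T:001", text = "hepatic tissue", scope = "EXACT"))
}

# a small index whose strings differ only in interior vowels or doubled
# consonants, so Double Metaphone codes collide heavily
dense_phonetic_ontology <- function() {
  stems <- c("bone marrow", "liver lobe", "renal duct")
  vowel_cycle <- c(a = "e", e = "i", i = "o", o = "u", u = "a")
  rotate_vowels <- function(s) {
    chars <- strsplit(s, "")[[1]]
    for (j in seq_along(chars)[-1]) {
      if (chars[[j]] %in% names(vowel_cycle) && chars[[j - 1]] != " ") {
        chars[[j]] <- vowel_cycle[[chars[[j]]]]
      }
    }
    paste(chars, collapse = "")
  }
  double_consonant <- function(s, which) {
    chars <- strsplit(s, "")[[1]]
    # doubling r/n/m/l never changes a Double Metaphone code
    pos <- which(chars %in% c("r", "n", "m", "l"))
    pos <- pos[pos > 1]
    if (length(pos) < which) return(character())
    i <- pos[[which]]
    paste(c(chars[seq_len(i)], chars[i:length(chars)]), collapse = "")
  }
  variants <- unlist(lapply(stems, function(s) {
    rots <- s
    cur <- s
    for (k in 1:4) {
      cur <- rotate_vowels(cur)
      rots <- c(rots, cur)
    }
    c(rots,
      unlist(lapply(rots, function(r) {
        c(double_consonant(r, 1L), double_consonant(r, 2L))
      })))
  }))
  variants <- unique(variants)
  as_ontology(tibble::tibble(
    id = sprintf("DP:%03d", seq_along(variants)),
    label = variants, obsolete = FALSE))
}
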