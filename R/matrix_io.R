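# Reading, validating and writing discrete morphological character matrices.
#
# A matrix is stored as a `char_matrix`: taxon names, a character table
# (printed 1-based index, label, optimization kind), and a cell grid encoded
# as integer bitmasks (bit s+1 set <=> state s allowed at that cell).
# Missing ('?') and inapplicable ('-') cells are both NA: fully ambiguous
# over the column's states.  Polymorphic cells carry more than one bit.

MISSING_SYMBOLS <- c("?", "-")

encode_states <- function(states) {
  if (length(states) == 0L) stop("empty state set in cell", call. = FALSE)
  sum(bitwShiftL(1L, as.integer(states)))
}

decode_mask <- function(mask) {
  if (is.na(mask)) return(NA_integer_)
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) > 0L) - 1L
}

#' Construct a validated character matrix
#'
#' Low-level constructor used by the parsers and the simulator.  `cells` is
#' an integer matrix of state bitmasks (bit s+1 set when state s is allowed;
#' `NA` = missing/inapplicable), with rows in taxon order and columns in
#' character order.
#'
#' @param taxa character vector of unique taxon names.
#' @param cells integer bitmask matrix, `length(taxa)` rows.
#' @param kinds character vector, one of `"binary"`, `"ordered"`,
#'   `"unordered"` per character.
#' @param labels optional character labels (free text).
#' @return A `char_matrix` object.
#' @export
char_matrix <- function(taxa, cells, kinds, labels = NULL) {
  cells <- matrix(as.integer(cells), nrow = length(taxa))
  ncha <- ncol(cells)
  if (anyDuplicated(taxa))
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1], call. = FALSE)
  if (length(kinds) != ncha)
    stop("need one kind per character", call. = FALSE)
  if (!all(kinds %in% c("binary", "ordered", "unordered")))
    stop("unknown character kind", call. = FALSE)
  if (is.null(labels)) labels <- paste("character", seq_len(ncha))
  domain <- lapply(seq_len(ncha), function(j) {
    masks <- cells[, j]
    sort(unique(unlist(lapply(masks[!is.na(masks)], decode_mask))))
  })
  bad <- which(kinds == "binary" & vapply(domain, length, 1L) > 2L)
  if (length(bad))
    stop("character ", bad[1], " is marked binary but has ",
         length(domain[[bad[1]]]), " states", call. = FALSE)
  structure(
    list(taxa = as.character(taxa),
         chars = data.frame(index = seq_len(ncha), label = labels,
                            kind = kinds, stringsAsFactors = FALSE),
         state_domain = domain,
         cells = cells),
    class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters\n",
              length(x$taxa), nrow(x$chars)))
  cat(sprintf("  kinds: %d binary, %d ordered, %d unordered\n",
              sum(x$chars$kind == "binary"), sum(x$chars$kind == "ordered"),
              sum(x$chars$kind == "unordered")))
  nmis <- sum(is.na(x$cells))
  npoly <- sum(vapply(x$cells[!is.na(x$cells)],
                      function(m) length(decode_mask(m)) > 1L, TRUE))
  cat(sprintf("  %d missing cells, %d polymorphic cells\n", nmis, npoly))
  invisible(x)
}

#' Number of taxa / characters
#' @param m a `char_matrix`.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_char <- function(m) nrow(m$chars)

#' States allowed in one cell
#'
#' @param m a `char_matrix`.
#' @param taxon taxon name or row index.
#' @param char 1-based character index.
#' @return Integer vector of allowed states, or `NA` for a missing cell.
#' @export
cell_states <- function(m, taxon, char) {
  if (is.character(taxon)) taxon <- match(taxon, m$taxa)
  decode_mask(m$cells[taxon, char])
}

# Tokenize a row of state symbols into bitmasks; bracket styles: [01] (TNT),
# (01) and {01} (NEXUS).  Returns integer vector with NA for ?/-.
tokenize_states <- function(text, taxon = "?", ncha_expected = NULL) {
  toks <- regmatches(text, gregexpr("\\[[0-9]+\\]|\\([0-9]+\\)|\\{[0-9]+\\}|[0-9?-]",
                                    text))[[1]]
  if (nchar(gsub("\\s", "", text)) != sum(nchar(toks)))
    stop("unknown symbol in states for taxon '", taxon, "'", call. = FALSE)
  masks <- vapply(toks, function(t) {
    if (t %in% MISSING_SYMBOLS) return(NA_integer_)
    digs <- as.integer(strsplit(gsub("[][}{)(]", "", t), "")[[1]])
    encode_states(unique(digs))
  }, 1L, USE.NAMES = FALSE)
  if (!is.null(ncha_expected) && length(masks) != ncha_expected)
    stop("taxon '", taxon, "' has ", length(masks), " cells, expected ",
         ncha_expected, call. = FALSE)
  masks
}

# kind assignment shared by both dialects: explicit declarations win, then
# two-state columns are binary and larger ones default to unordered
assign_kinds <- function(ncha, domain, ord_idx, unord_idx) {
  kinds <- ifelse(vapply(domain, length, 1L) <= 2L, "binary", "unordered")
  kinds[ord_idx] <- "ordered"
  kinds[unord_idx] <- "unordered"
  kinds
}

#' Parse a character-matrix document
#'
#' Two dialects are supported.  `"nexus"`: a `DATA`/`CHARACTERS` block with
#' `DIMENSIONS`, `FORMAT SYMBOLS="0~4" MISSING=? GAP=-` and a `MATRIX` with
#' one taxon per line (names may be single-quoted); polymorphism as `(01)`
#' or `{01}`; an optional `ASSUMPTIONS` block
#' `TYPESET * default = ord: <1-based indices>, unord: <indices>;` declares
#' optimization kinds.  `"tnt"`: an `xread`-style file whose header line is
#' `<ncharacters> <ntaxa>`, rows `taxon<whitespace>states` with `[01]`
#' polymorphism (underscores in names are read as spaces), and optional
#' `ccode + <0-based indices>;` / `ccode - <indices>;` lines declaring
#' additive / nonadditive characters.
#'
#' Characters not covered by a declaration default to unordered, stored as
#' `"binary"` when at most two states are observed (the costs coincide).
#' `?` and `-` cells both become missing.
#'
#' @param text document text (single string or vector of lines).
#' @param dialect `"nexus"` or `"tnt"`.
#' @return A `char_matrix`.
#' @export
parse_matrix <- function(text, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  text <- paste(text, collapse = "\n")
  if (dialect == "nexus") parse_nexus(text) else parse_tnt(text)
}

parse_nexus <- function(text) {
  if (!grepl("#NEXUS", text, ignore.case = TRUE))
    stop("not a NEXUS document", call. = FALSE)
  # strip [] comments (polymorphism uses parentheses/braces in this dialect)
  text <- gsub("\\[[^]]*\\]", "", text)
  dims <- regmatches(text, regexpr("DIMENSIONS[^;]*;", text, ignore.case = TRUE))
  if (!length(dims)) stop("missing DIMENSIONS statement", call. = FALSE)
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dims, ignore.case = TRUE))
  ncha <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dims, ignore.case = TRUE))
  mat <- regmatches(text, regexpr("(?is)MATRIX.*?;", text, perl = TRUE))
  if (!length(mat)) stop("missing MATRIX block", call. = FALSE)
  rows <- strsplit(mat, "\n")[[1]]
  rows <- trimws(rows[-1])
  rows <- rows[nzchar(rows) & rows != ";"]
  rows <- sub(";\\s*$", "", rows)
  rows <- rows[nzchar(rows)]
  if (length(rows) != ntax)
    stop("MATRIX has ", length(rows), " rows, DIMENSIONS says NTAX=", ntax,
         call. = FALSE)
  taxa <- character(ntax)
  cells <- matrix(NA_integer_, ntax, ncha)
  for (i in seq_len(ntax)) {
    row <- rows[i]
    if (startsWith(row, "'")) {
      end <- regexpr("'", substring(row, 2), fixed = TRUE)
      if (end < 0) stop("unterminated quoted taxon name", call. = FALSE)
      taxa[i] <- substr(row, 2, end)
      rest <- substring(row, end + 2)
    } else {
      sp <- regexpr("\\s", row)
      if (sp < 0) stop("row without states: ", row, call. = FALSE)
      taxa[i] <- substr(row, 1, sp - 1)
      rest <- substring(row, sp + 1)
    }
    cells[i, ] <- tokenize_states(trimws(rest), taxa[i], ncha)
  }
  ord_idx <- unord_idx <- integer(0)
  ts <- regmatches(text, regexpr("TYPESET[^;]*;", text, ignore.case = TRUE))
  if (length(ts)) {
    grab <- function(key) {
      mm <- regmatches(ts, regexpr(paste0("\\b", key, "\\s*:[0-9 \t]*"), ts,
                                   ignore.case = TRUE))
      if (!length(mm)) return(integer(0))
      as.integer(strsplit(trimws(sub(".*?:", "", mm)), "\\s+")[[1]])
    }
    ord_idx <- grab("ord")
    unord_idx <- grab("unord")
  }
  domain <- lapply(seq_len(ncha), function(j) {
    mk <- cells[, j]
    sort(unique(unlist(lapply(mk[!is.na(mk)], decode_mask))))
  })
  char_matrix(taxa, cells, assign_kinds(ncha, domain, ord_idx, unord_idx))
}

parse_tnt <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^xread", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr))))
    stop("TNT header must be '<nchar> <ntax>'", call. = FALSE)
  ncha <- as.integer(hdr[1]); ntax <- as.integer(hdr[2])
  body <- lines[-1]
  ccode <- body[grepl("^ccode", body, ignore.case = TRUE)]
  rows <- body[!grepl("^ccode|^;$|^proc", body, ignore.case = TRUE)]
  rows <- sub(";\\s*$", "", rows)
  rows <- rows[nzchar(rows)]
  if (length(rows) != ntax)
    stop("matrix has ", length(rows), " rows, header says ", ntax, call. = FALSE)
  taxa <- character(ntax)
  cells <- matrix(NA_integer_, ntax, ncha)
  for (i in seq_len(ntax)) {
    sp <- regexpr("\\s", rows[i])
    if (sp < 0) stop("row without states: ", rows[i], call. = FALSE)
    taxa[i] <- gsub("_", " ", substr(rows[i], 1, sp - 1))
    cells[i, ] <- tokenize_states(trimws(substring(rows[i], sp + 1)),
                                  taxa[i], ncha)
  }
  ord_idx <- unord_idx <- integer(0)
  for (cc in ccode) {
    cc <- sub(";\\s*$", "", cc)
    parts <- strsplit(trimws(sub("(?i)^ccode", "", cc, perl = TRUE)), "\\s+")[[1]]
    if (length(parts) < 2) next
    idx <- as.integer(parts[-1]) + 1L  # TNT character numbers are 0-based
    if (parts[1] == "+") ord_idx <- c(ord_idx, idx)
    if (parts[1] == "-") unord_idx <- c(unord_idx, idx)
  }
  domain <- lapply(seq_len(ncha), function(j) {
    mk <- cells[, j]
    sort(unique(unlist(lapply(mk[!is.na(mk)], decode_mask))))
  })
  char_matrix(taxa, cells, assign_kinds(ncha, domain, ord_idx, unord_idx))
}

mask_to_symbol <- function(mask, dialect) {
  if (is.na(mask)) return("?")
  st <- decode_mask(mask)
  if (length(st) == 1) return(as.character(st))
  inner <- paste(st, collapse = "")
  if (dialect == "nexus") paste0("(", inner, ")") else paste0("[", inner, "]")
}

#' Write a character matrix document
#'
#' Inverse of [parse_matrix()]: `parse_matrix(write_matrix(m, d), d)` is
#' cell-for-cell and kind-for-kind identical to `m`.  Missing cells are
#' written as `?`.  In the TNT dialect spaces in taxon names become
#' underscores.
#'
#' @param m a `char_matrix`.
#' @param dialect `"nexus"` or `"tnt"`.
#' @param file optional path; when given the document is also written there.
#' @return The document as a single string (invisibly when `file` is given).
#' @export
write_matrix <- function(m, dialect = c("nexus", "tnt"), file = NULL) {
  dialect <- match.arg(dialect)
  ntax <- n_taxa(m); ncha <- n_char(m)
  rows <- vapply(seq_len(ntax), function(i)
    paste(vapply(m$cells[i, ], mask_to_symbol, "", dialect = dialect),
          collapse = ""), "")
  ord_idx <- which(m$chars$kind == "ordered")
  unord_idx <- which(m$chars$kind == "unordered")
  if (dialect == "nexus") {
    names_q <- paste0("'", m$taxa, "'")
    pad <- max(nchar(names_q)) + 2
    maxst <- max(c(0L, unlist(m$state_domain)))
    doc <- c("#NEXUS", "", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", ntax, ncha),
             sprintf("  FORMAT SYMBOLS=\"0~%d\" MISSING=? GAP=-;", maxst),
             "  MATRIX",
             paste0("  ", formatC(names_q, width = -pad), rows),
             "  ;", "END;")
    if (length(ord_idx) || length(unord_idx)) {
      parts <- c(if (length(ord_idx)) paste("ord:", paste(ord_idx, collapse = " ")),
                 if (length(unord_idx)) paste("unord:", paste(unord_idx, collapse = " ")))
      doc <- c(doc, "", "BEGIN ASSUMPTIONS;",
               sprintf("  TYPESET * default = %s;", paste(parts, collapse = ", ")),
               "END;")
    }
  } else {
    names_u <- gsub(" ", "_", m$taxa)
    pad <- max(nchar(names_u)) + 2
    doc <- c("xread", sprintf("%d %d", ncha, ntax),
             paste0(formatC(names_u, width = -pad), rows), ";")
    if (length(ord_idx))
      doc <- c(doc, sprintf("ccode + %s;", paste(ord_idx - 1L, collapse = " ")))
    if (length(unord_idx))
      doc <- c(doc, sprintf("ccode - %s;", paste(unord_idx - 1L, collapse = " ")))
  }
  out <- paste(doc, collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# md5 of the bundled fixture, frozen at transcription time to guard against
# accidental drift of the shipped file
MORIOMORPHINI_MD5 <- "a6ebc7a1283523228402d69b79a068c1"

MORIOMORPHINI_LABELS <- c(
  "Labrum apical margin", "Mandibular length",
  "Mandibular scrobe ventral margin", "Apical maxillary palps",
  "Maxillary stipes", "Lacinial apex", "Glossal sclerite of ligula",
  "Ligular setae across apex of glossal sclerite", "Paraglossae of ligula",
  "Paraglossal articulation with glossal sclerite",
  "Paraglossae of ligula setation", "Mentum lateral lobes depth",
  "Mentum lateral lobes expansion", "Mentum medial tooth",
  "Mentum paramedial depression", "Antennae", "Supraorbital setae",
  "Frontal grooves", "Vertex microsculpture", "Pronotal basolateral seta",
  "Pronotal lateral seta position", "Pronotal lateral seta placement",
  "Basolateral margin", "Pronotal base", "Pronotal basal margin",
  "Mesepisternum", "Pronotal discal microsculpture",
  "Prosternal process setation", "Prosternal process keel",
  "Mesothoracic scutellum", "Parascutellar striole",
  "Elytral basal groove and margin", "Elytral humerus", "Elytral striae",
  "Elytral striae at apex", "Elytral striae punctation",
  "7th stria and 8th interval", "Fifth elytral stria",
  "Subapical sinuation", "Elytral internal plica",
  "Basal elytral dorsal seta", "Apical dorsal elytral seta",
  "Apical elytral setae", "Elytral lateral setae",
  "Elytral discal microsculpture", "Mid-interval microsculpture",
  "Metathoracic flight wings", "Metepisternum-metepimeron juncture",
  "Mesotibiae", "Metatrochanteral apex", "Tarsomeres dorsal surface",
  "Tarsomeres compression", "Male ventral protarsal vestiture",
  "Marginal setae of apical ventrite, male",
  "Marginal setae of apical ventrite, female",
  "Medial subapical setal patch, female",
  "Abdominal ventrite lateral depressions", "Ventral paramere shape",
  "Dorsal paramere shape", "Ventral paramere setation",
  "Dorsal paramere setation", "Internal sac flagellum",
  "Flagellum configuration", "Aedeagal median lobe tip",
  "Bursa copulatrix shape", "Spermathecal placement",
  "Helminthoid sclerite", "Spermathecal duct length", "Spermathecal shape",
  "Spermathecal gland", "Ramus", "Lateroapical fringe of gonocoxite 1",
  "Medial setae of gonocoxite 1", "Lateral ensiform setae of gonocoxite 2",
  "Apical sensory furrow")

#' The bundled Moriomorphini matrix
#'
#' Loads the 22-taxon by 75-character morphological matrix for the tribe
#' Moriomorphini (21 ingroup taxa plus the outgroup *Trechus obtusus*,
#' which is taxon 1).  Multistate characters are additive (ordered) or
#' nonadditive (unordered) as flagged in the published character list;
#' unflagged characters are binary.  The three polymorphic terminals and
#' all `?`/`-` cells of the printed table are preserved.
#'
#' @return A `char_matrix` with 22 taxa and 75 characters.
#' @export
load_moriomorphini <- function() {
  path <- system.file("extdata", "moriomorphini.nex", package = "moriomorph",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, MORIOMORPHINI_MD5))
    stop("bundled Moriomorphini matrix fails its content checksum (",
         md5, "); the installed file has drifted", call. = FALSE)
  m <- parse_matrix(readLines(path), "nexus")
  m$chars$label <- MORIOMORPHINI_LABELS
  m
}
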