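#' @title GenBank flat-file parser (FTv8 dialect)
#' @description Streaming indexer and regular-expression based parser for
#'   GenBank flat files following the DDBJ/EMBL/GenBank Feature Table
#'   definition v8.  An entry is split into four contiguous sections
#'   (header, references, feature table, sequence) which are parsed by
#'   content-specific functions into a structured [gb_entry] object.
#' @name genbank-parser
NULL

MONTHS3 <- c(JAN = 1L, FEB = 2L, MAR = 3L, APR = 4L, MAY = 5L, JUN = 6L,
             JUL = 7L, AUG = 8L, SEP = 9L, OCT = 10L, NOV = 11L, DEC = 12L)

#' Index the entries of a GenBank flat file
#'
#' Scans a flat file once, recording for every LOCUS..// block the byte
#' offset of its first line, the byte offset of the first nucleotide of its
#' sequence, and its GI number.  These records are the unit of job dispatch:
#' a loader can seek straight to an entry without re-reading the file.
#'
#' The scan is streaming: memory is bounded by the read chunk, not the file.
#'
#' @param path path to a GenBank flat file.
#' @param chunk_lines number of lines read per chunk.
#' @return a data.frame with columns `header_offset`, `sequence_offset`
#'   (NA when the entry has no ORIGIN block) and `gi`, one row per entry in
#'   file order.
#' @export
gb_index_entries <- function(path, chunk_lines = 4096L) {
  stopifnot(file.exists(path))
  con <- file(path, open = "r")
  on.exit(close(con))
  offset <- 0L
  in_entry <- FALSE
  await_seq <- FALSE
  cur <- list(header_offset = NA_integer_, sequence_offset = NA_integer_,
              gi = NA_integer_)
  out <- list()
  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (length(lines) == 0L) break
    for (ln in lines) {
      nb <- nchar(ln, type = "bytes") + 1L  # trailing newline
      if (startsWith(ln, "LOCUS")) {
        in_entry <- TRUE
        cur <- list(header_offset = offset, sequence_offset = NA_integer_,
                    gi = NA_integer_)
      } else if (in_entry && startsWith(ln, "VERSION")) {
        m <- regmatches(ln, regexec("GI:(\\d+)", ln))[[1]]
        if (length(m) == 2L) cur$gi <- as.integer(m[2])
      } else if (in_entry && startsWith(ln, "ORIGIN")) {
        await_seq <- TRUE
      } else if (await_seq && !startsWith(ln, "//")) {
        p <- regexpr("[A-Za-z]", ln)
        if (p > 0L) {
          cur$sequence_offset <- offset + as.integer(p) - 1L
          await_seq <- FALSE
        }
      }
      if (startsWith(ln, "//")) {
        if (!in_entry)
          stop("malformed flat file: '//' with no preceding LOCUS at byte offset ",
               offset, " in ", path)
        out[[length(out) + 1L]] <- cur
        in_entry <- FALSE
        await_seq <- FALSE
      }
      offset <- offset + nb
    }
  }
  if (in_entry)
    stop("malformed flat file: entry starting at byte offset ",
         cur$header_offset, " has no terminating '//' in ", path)
  if (length(out) == 0L)
    return(data.frame(header_offset = integer(0), sequence_offset = integer(0),
                      gi = integer(0)))
  data.frame(header_offset = vapply(out, `[[`, integer(1), "header_offset"),
             sequence_offset = vapply(out, `[[`, integer(1), "sequence_offset"),
             gi = vapply(out, `[[`, integer(1), "gi"))
}

#' Read the raw text of one entry starting at a byte offset
#'
#' @param path flat file path.
#' @param offset byte offset of the entry's LOCUS line (from
#'   [gb_index_entries()]).
#' @return the entry text, LOCUS through `//`.
#' @export
gb_read_entry_at <- function(path, offset) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = offset, origin = "start")
  tcon <- NULL
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) break
    lines <- c(lines, ln)
    if (startsWith(ln, "//")) break
  }
  if (length(lines) == 0L || !startsWith(lines[1L], "LOCUS"))
    stop("byte offset ", offset, " in ", path, " does not start a LOCUS line")
  paste(lines, collapse = "\n")
}

#' Split one entry into its four sections
#'
#' Localizes the header, references, feature table and sequence portions of
#' a LOCUS..// block.  The sections are contiguous slices of the input, so
#' their concatenation reproduces the entry.
#'
#' @param entry_text text of one entry (LOCUS through `//`).
#' @return a list with `header_text`, `references_text`, `features_text`,
#'   `sequence_text`.
#' @export
gb_split_entry <- function(entry_text) {
  lines <- strsplit(entry_text, "\n", fixed = TRUE)[[1]]
  i_ref <- which(startsWith(lines, "REFERENCE"))[1]
  i_fea <- which(startsWith(lines, "FEATURES"))[1]
  i_ori <- which(startsWith(lines, "ORIGIN"))[1]
  i_end <- which(startsWith(lines, "//"))[1]
  if (is.na(i_ori))
    stop("entry parse error: missing ORIGIN section")
  if (is.na(i_end))
    stop("entry parse error: missing '//' terminator (sequence section)")
  hdr_end <- min(i_ref, i_fea, i_ori, na.rm = TRUE) - 1L
  ref_end <- min(i_fea, i_ori, na.rm = TRUE) - 1L
  join <- function(ix) if (length(ix) == 0L) "" else paste(lines[ix], collapse = "\n")
  list(
    header_text     = join(seq_len(hdr_end)),
    references_text = if (is.na(i_ref)) "" else join(seq(i_ref, ref_end)),
    features_text   = if (is.na(i_fea)) "" else join(seq(i_fea, i_ori - 1L)),
    sequence_text   = join(seq(i_ori, i_end))
  )
}

# continuation block: field value lines joined until the next top-level field
gb_field_block <- function(lines, i) {
  vals <- sub("^\\S+\\s*", "", lines[i])
  j <- i + 1L
  while (j <= length(lines) && grepl("^\\s{2,}\\S", lines[j])) {
    vals <- c(vals, trimws(lines[j]))
    j <- j + 1L
  }
  paste(trimws(vals), collapse = " ")
}

#' Parse the header section of an entry
#'
#' Applies regular expressions to the LOCUS/DEFINITION/ACCESSION/VERSION/
#' KEYWORDS/SOURCE/ORGANISM lines.  Absent optional fields are set to
#' explicit empty markers (`""`, `NA`, or zero-length vectors).
#'
#' @param header_text the header section from [gb_split_entry()].
#' @return a list with locus_name, sequence_length, molecule_type, topology,
#'   division_code, modification_date (ISO string), definition, accession,
#'   version, gi, keywords, organism_name, lineage.
#' @export
gb_parse_header <- function(header_text) {
  lines <- strsplit(header_text, "\n", fixed = TRUE)[[1]]
  locus <- lines[startsWith(lines, "LOCUS")][1]
  if (is.na(locus)) stop("header parse error: no LOCUS line")
  m <- regmatches(locus, regexec(
    "^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp\\s+(\\S+)?\\s+(linear|circular)\\s+(\\S{3})\\s+(\\d{2}-[A-Z]{3}-\\d{4})",
    locus))[[1]]
  if (length(m) == 0L) {
    # tolerate missing molecule type / date variants
    m <- regmatches(locus, regexec(
      "^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", locus))[[1]]
    if (length(m) == 0L)
      stop("header parse error: unparseable LOCUS line: ", locus)
    m <- c(m, "", "linear", "UNK", "")
  }
  date_iso <- ""
  if (nzchar(m[7])) {
    dd <- strsplit(m[7], "-", fixed = TRUE)[[1]]
    date_iso <- sprintf("%s-%02d-%s", dd[3], MONTHS3[[dd[2]]], dd[1])
  }
  grab <- function(tag) {
    i <- which(startsWith(lines, tag))[1]
    if (is.na(i)) "" else gb_field_block(lines, i)
  }
  version_line <- lines[startsWith(lines, "VERSION")][1]
  version <- ""
  gi <- NA_integer_
  if (!is.na(version_line)) {
    vm <- regmatches(version_line,
                     regexec("^VERSION\\s+(\\S+)(?:\\s+GI:(\\d+))?", version_line))[[1]]
    version <- vm[2]
    if (length(vm) >= 3L && nzchar(vm[3])) gi <- as.integer(vm[3])
  }
  kw <- grab("KEYWORDS")
  kw <- sub("\\.\\s*$", "", kw)
  keywords <- if (nzchar(kw)) trimws(strsplit(kw, ";", fixed = TRUE)[[1]]) else character(0)
  # ORGANISM subblock: first line is the binomial, the indented continuation
  # is the lineage, terminated by a period.
  organism_name <- ""
  lineage <- character(0)
  i_org <- which(grepl("^\\s{2}ORGANISM", lines))[1]
  if (!is.na(i_org)) {
    organism_name <- trimws(sub("^\\s*ORGANISM\\s*", "", lines[i_org]))
    j <- i_org + 1L
    lin <- character(0)
    while (j <= length(lines) && grepl("^\\s{4,}\\S", lines[j])) {
      lin <- c(lin, trimws(lines[j]))
      j <- j + 1L
    }
    if (length(lin)) {
      lin <- sub("\\.\\s*$", "", paste(lin, collapse = " "))
      lineage <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    }
  }
  list(
    locus_name = m[2],
    sequence_length = as.integer(m[3]),
    molecule_type = m[4],
    topology = m[5],
    division_code = m[6],
    modification_date = date_iso,
    definition = sub("\\.\\s*$", "", grab("DEFINITION")),
    accession = sub("\\s.*$", "", grab("ACCESSION")),
    version = version,
    gi = gi,
    keywords = keywords,
    organism_name = organism_name,
    lineage = lineage
  )
}

#' Parse the references section of an entry
#'
#' Splits the section into single REFERENCE blocks and extracts, per block,
#' the ordinal, the cited base ranges from the `(bases X to Y; ...)` clause,
#' and the AUTHORS/TITLE/JOURNAL/PUBMED fields.  A block without a parsable
#' base clause gets zero ranges and `whole_entry = TRUE`; the caller widens
#' it to the whole entry span (see [gb_parse_entry()]).
#'
#' @param references_text the references section (may be empty).
#' @return a list of reference records.
#' @export
gb_parse_references <- function(references_text) {
  if (!nzchar(trimws(references_text))) return(list())
  lines <- strsplit(references_text, "\n", fixed = TRUE)[[1]]
  starts <- which(startsWith(lines, "REFERENCE"))
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    head_line <- blk[1]
    om <- regmatches(head_line, regexec("^REFERENCE\\s+(\\d+)", head_line))[[1]]
    ordinal <- if (length(om) == 2L) as.integer(om[2]) else k
    ranges <- NULL
    bm <- regmatches(head_line, regexec("\\(bases\\s+([0-9;to ]+)\\)", head_line))[[1]]
    if (length(bm) == 2L) {
      pieces <- regmatches(bm[2], gregexpr("(\\d+)\\s+to\\s+(\\d+)", bm[2]))[[1]]
      if (length(pieces)) {
        ranges <- do.call(rbind, lapply(pieces, function(p) {
          xy <- as.integer(regmatches(p, gregexpr("\\d+", p))[[1]])
          data.frame(start = xy[1], end = xy[2])
        }))
      }
    }
    sub_lines <- blk[-1]
    grab <- function(tag) {
      i <- which(grepl(paste0("^\\s{2,}", tag, "\\b"), sub_lines))[1]
      if (is.na(i)) return("")
      vals <- sub("^\\s*\\S+\\s*", "", sub_lines[i])
      j <- i + 1L
      while (j <= length(sub_lines) && grepl("^\\s{4,}\\S", sub_lines[j]) &&
             !grepl("^\\s{2}[A-Z]+\\s", sub_lines[j])) {
        vals <- c(vals, trimws(sub_lines[j]))
        j <- j + 1L
      }
      paste(trimws(vals), collapse = " ")
    }
    pm <- grab("PUBMED")
    list(ordinal = ordinal,
         cited_ranges = if (is.null(ranges))
           data.frame(start = integer(0), end = integer(0)) else ranges,
         whole_entry = is.null(ranges),
         authors = grab("AUTHORS"),
         title = grab("TITLE"),
         journal = grab("JOURNAL"),
         pubmed_id = if (nzchar(pm)) as.integer(sub("\\D.*$", "", pm)) else NA_integer_)
  })
}

#' Parse an FTv8 feature location string
#'
#' Recursive-descent parser for the FTv8 location grammar: points, ranges,
#' `join()`, `order()`, `complement()`, fuzzy ends (`<`, `>`), between-base
#' positions (`^`) and remote accession-qualified spans.  `complement()`
#' flips the strand of every enclosed portion but preserves textual portion
#' order; nested `complement(complement(...))` is rejected as malformed.
#' `order()` is treated like `join()` with a `location_operator` attribute.
#'
#' @param location_text the location string.
#' @return a data.frame of portions with columns start, end, strand
#'   ("forward"/"reverse"), partial5, partial3, between_bases,
#'   remote_accession (NA if local) and rank (0-based, ascending); attribute
#'   `location_operator` is "order" when order() was used.
#' @export
gb_parse_location <- function(location_text) {
  s <- gsub("\\s", "", location_text)
  if (!nzchar(s)) stop("location parse error: empty location string")
  if (lengths(regmatches(s, gregexpr("(", s, fixed = TRUE))) !=
      lengths(regmatches(s, gregexpr(")", s, fixed = TRUE))))
    stop("location parse error: unbalanced parentheses in '", location_text, "'")
  operator <- NULL

  parse_node <- function(str, complemented) {
    if (startsWith(str, "complement(")) {
      inner <- substr(str, 12L, nchar(str) - 1L)
      if (complemented)
        stop("location parse error: nested complement() in '", location_text, "'")
      return(parse_node(inner, TRUE))
    }
    if (startsWith(str, "join(") || startsWith(str, "order(")) {
      if (startsWith(str, "order(")) operator <<- "order"
      inner <- substr(str, regexpr("(", str, fixed = TRUE) + 1L, nchar(str) - 1L)
      parts <- split_args(inner)
      return(do.call(rbind, lapply(parts, parse_node, complemented = complemented)))
    }
    if (grepl("^(complement|join|order)$", sub("\\(.*", "", str)) == FALSE &&
        grepl("^[A-Za-z]+[A-Za-z0-9_.]*\\(", str))
      stop("location parse error: unknown operator in '", location_text, "'")
    parse_simple(str, complemented)
  }

  split_args <- function(str) {
    depth <- 0L
    cuts <- integer(0)
    chars <- strsplit(str, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      else if (chars[i] == ")") depth <- depth - 1L
      else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
    }
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts - 1L, nchar(str))
    mapply(function(a, b) substr(str, a, b), starts, ends,
           USE.NAMES = FALSE, SIMPLIFY = TRUE)
  }

  parse_simple <- function(str, complemented) {
    remote <- NA_character_
    rm_ <- regmatches(str, regexec("^([A-Za-z][A-Za-z0-9_.]*):(.*)$", str))[[1]]
    if (length(rm_) == 3L) {
      remote <- rm_[2]
      str <- rm_[3]
    }
    strand <- if (complemented) "reverse" else "forward"
    mk <- function(start, end, p5 = FALSE, p3 = FALSE, between = FALSE) {
      data.frame(start = start, end = end, strand = strand,
                 partial5 = p5, partial3 = p3, between_bases = between,
                 remote_accession = remote, stringsAsFactors = FALSE)
    }
    m <- regmatches(str, regexec("^(\\d+)\\^(\\d+)$", str))[[1]]
    if (length(m) == 3L) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (b != a + 1L)
        stop("location parse error: between-base position must be adjacent in '",
             location_text, "'")
      return(mk(a, b, between = TRUE))
    }
    m <- regmatches(str, regexec("^(<?)(\\d+)\\.\\.(>?)(\\d+)$", str))[[1]]
    if (length(m) == 5L) {
      a <- as.integer(m[3]); b <- as.integer(m[5])
      if (a > b)
        stop("location parse error: start > end in '", location_text, "'")
      return(mk(a, b, p5 = nzchar(m[2]), p3 = nzchar(m[4])))
    }
    m <- regmatches(str, regexec("^(<?)(\\d+)(>?)$", str))[[1]]
    if (length(m) == 4L) {
      a <- as.integer(m[3])
      return(mk(a, a, p5 = nzchar(m[2]), p3 = nzchar(m[4])))
    }
    stop("location parse error: cannot parse '", str, "' in '", location_text, "'")
  }

  out <- parse_node(s, FALSE)
  out$rank <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  if (!is.null(operator)) attr(out, "location_operator") <- operator
  out
}

#' Parse the feature table section of an entry
#'
#' Feature key lines are indexed first (key at column 6, location at column
#' 22), then each feature's location and qualifier block is parsed.
#' Multi-line qualifier values are joined with a single space, except
#' `/translation` which is joined with no separator; quoted values are
#' unquoted; flag qualifiers carry an NA value.
#'
#' @param features_text the feature table section (may be empty).
#' @param mapping optional feature-key mapping (see [gb_feature_key_mapping()])
#'   used only to flag unknown keys; keys are not rejected.
#' @return a list of features, each a list with key, portions (data.frame per
#'   [gb_parse_location()]), qualifiers (data.frame name/value), rank
#'   (0-based) and unknown_key flag.
#' @export
gb_parse_feature_table <- function(features_text, mapping = NULL) {
  if (!nzchar(trimws(features_text))) return(list())
  lines <- strsplit(features_text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(lines, "FEATURES")]
  if (length(lines) == 0L) return(list())
  is_key <- grepl("^ {5}\\S", lines)
  if (!is_key[1])
    stop("feature table parse error: continuation or qualifier line before any feature key")
  idx <- which(is_key)
  ends <- c(idx[-1] - 1L, length(lines))
  known <- if (is.null(mapping)) NULL else mapping$feature_key
  feats <- lapply(seq_along(idx), function(k) {
    blk <- lines[idx[k]:ends[k]]
    km <- regmatches(blk[1], regexec("^ {5}(\\S+)\\s+(\\S.*)$", blk[1]))[[1]]
    if (length(km) != 3L)
      stop("feature table parse error: unparseable feature line: ", blk[1])
    key <- km[2]
    loc <- km[3]
    rest <- if (length(blk) > 1L) trimws(blk[-1]) else character(0)
    # location may wrap onto continuation lines until the first /qualifier
    qi <- 1L
    while (qi <= length(rest) && !startsWith(rest[qi], "/")) {
      loc <- paste0(loc, rest[qi])
      qi <- qi + 1L
    }
    quals <- list()
    cur_name <- NULL
    cur_val <- NULL
    cur_quoted <- FALSE
    open_quote <- FALSE
    flush_q <- function() {
      if (!is.null(cur_name)) {
        val <- if (is.null(cur_val)) NA_character_ else {
          sep <- if (identical(cur_name, "translation")) "" else " "
          v <- paste(cur_val, collapse = sep)
          if (cur_quoted) v <- gsub("\"\"", "\"", v)
          v
        }
        quals[[length(quals) + 1L]] <<- list(name = cur_name, value = val)
      }
      cur_name <<- NULL; cur_val <<- NULL; cur_quoted <<- FALSE; open_quote <<- FALSE
    }
    while (qi <= length(rest)) {
      ln <- rest[qi]
      if (startsWith(ln, "/") && !open_quote) {
        flush_q()
        qm <- regmatches(ln, regexec("^/([A-Za-z_][A-Za-z0-9_]*)(=(.*))?$", ln))[[1]]
        if (length(qm) < 2L)
          stop("feature table parse error: unparseable qualifier line: ", ln)
        cur_name <- qm[2]
        if (nzchar(qm[3])) {
          v <- qm[4]
          if (startsWith(v, "\"")) {
            cur_quoted <- TRUE
            v <- substr(v, 2L, nchar(v))
            if (endsWith(v, "\"") && !endsWith(v, "\"\"")) {
              v <- substr(v, 1L, nchar(v) - 1L)
            } else open_quote <- TRUE
          }
          cur_val <- v
        }
      } else {
        # continuation of the current qualifier value
        v <- ln
        if (open_quote && endsWith(v, "\"") && !endsWith(v, "\"\"")) {
          v <- substr(v, 1L, nchar(v) - 1L)
          open_quote <- FALSE
        }
        cur_val <- c(cur_val, v)
      }
      qi <- qi + 1L
    }
    flush_q()
    portions <- gb_parse_location(loc)
    qdf <- if (length(quals))
      data.frame(name = vapply(quals, `[[`, character(1), "name"),
                 value = vapply(quals, `[[`, character(1), "value"),
                 stringsAsFactors = FALSE)
    else data.frame(name = character(0), value = character(0))
    list(key = key,
         portions = portions,
         qualifiers = qdf,
         rank = k - 1L,
         location_operator = attr(portions, "location_operator"),
         unknown_key = if (is.null(known)) NA else !(key %in% known))
  })
  feats
}

#' Parse a whole GenBank entry
#'
#' Composes [gb_split_entry()], [gb_parse_header()], [gb_parse_references()]
#' and [gb_parse_feature_table()] and extracts the nucleotide sequence from
#' the ORIGIN block (digits and spacing stripped, lowercased).  References
#' without a parsable base clause are widened to the whole entry span
#' `[1, sequence_length]` with a warning.
#'
#' @param entry_text text of one entry (LOCUS through `//`).
#' @param mapping optional feature-key mapping used to flag unknown keys.
#' @return an object of class `gb_entry`: list(header, references, features,
#'   sequence).
#' @export
gb_parse_entry <- function(entry_text, mapping = NULL) {
  sections <- tryCatch(gb_split_entry(entry_text), error = function(e) {
    gi <- regmatches(entry_text, regexec("GI:(\\d+)", entry_text))[[1]]
    gi <- if (length(gi) == 2L) gi[2] else "?"
    stop("entry (gi ", gi, "): ", conditionMessage(e), call. = FALSE)
  })
  header <- gb_parse_header(sections$header_text)
  refs <- gb_parse_references(sections$references_text)
  for (i in seq_along(refs)) {
    if (refs[[i]]$whole_entry) {
      warning("entry (gi ", header$gi, "): reference ", refs[[i]]$ordinal,
              " has no parsable base clause; assigned whole-entry range [1, ",
              header$sequence_length, "]")
      refs[[i]]$cited_ranges <- data.frame(start = 1L,
                                           end = header$sequence_length)
    }
  }
  features <- gb_parse_feature_table(sections$features_text, mapping)
  seq_lines <- strsplit(sections$sequence_text, "\n", fixed = TRUE)[[1]]
  seq_lines <- seq_lines[!startsWith(seq_lines, "ORIGIN") & !startsWith(seq_lines, "//")]
  sequence <- tolower(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nzchar(sequence) && nchar(sequence) != header$sequence_length)
    stop("entry (gi ", header$gi, "): sequence length ", nchar(sequence),
         " does not match LOCUS declaration ", header$sequence_length)
  structure(list(header = header, references = refs, features = features,
                 sequence = sequence),
            class = "gb_entry")
}

#' @export
print.gb_entry <- function(x, ...) {
  cat("GenBank entry ", x$header$accession,
      " (gi ", x$header$gi, "): ", x$header$sequence_length, " bp, ",
      length(x$features), " features, ", length(x$references),
      " references\n", sep = "")
  invisible(x)
}

#' Read and parse every entry of a flat file
#'
#' @param path flat file path.
#' @param mapping optional feature-key mapping.
#' @return list of `gb_entry` objects in file order.
#' @export
gb_read_entries <- function(path, mapping = NULL) {
  idx <- gb_index_entries(path)
  lapply(idx$header_offset, function(off)
    gb_parse_entry(gb_read_entry_at(path, off), mapping))
}
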