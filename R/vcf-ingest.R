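## VCF ingestion: header-metadata-driven parsing of records into typed
## variant documents, whole-file validation with line numbers, and
## multi-allelic normalization to one alternate allele per row.

.CORE_COLS <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO")

.emptyFieldFrame <- function() {
  data.frame(id = character(0), number = character(0),
             type = character(0), description = character(0),
             stringsAsFactors = FALSE)
}

## Parse the key=value payload of a structured ##INFO/##FORMAT/##FILTER
## line, respecting a quoted Description that may contain commas.
.parseStructuredLine <- function(line, section, lineNumber) {
  inner <- sub(sprintf("^##%s=<", section), "", line)
  inner <- sub(">$", "", inner)
  id <- sub('.*(^|,)ID=([^,>]+).*', "\\2", inner)
  if (identical(id, inner) || !nzchar(id))
    stop(sprintf("line %d: malformed ##%s declaration (no ID): %s",
                 lineNumber, section, line))
  getAttr <- function(key) {
    m <- regmatches(inner,
                    regexec(sprintf("(^|,)%s=([^,\"]+|\"[^\"]*\")", key),
                            inner))[[1]]
    if (length(m) < 3) return(NA_character_)
    gsub('^"|"$', "", m[3])
  }
  number <- getAttr("Number")
  type <- getAttr("Type")
  if (section %in% c("INFO", "FORMAT")) {
    if (is.na(type))
      stop(sprintf("line %d: ##%s declaration for '%s' lacks Type=",
                   lineNumber, section, id))
    if (!type %in% c("Integer", "Float", "Flag", "String", "Character"))
      stop(sprintf("line %d: ##%s '%s' has invalid Type '%s'",
                   lineNumber, section, id, type))
    if (is.na(number)) number <- "."
  }
  data.frame(id = id, number = number, type = type,
             description = getAttr("Description"),
             stringsAsFactors = FALSE)
}

#' Parse VCF header lines into a VcfHeader
#'
#' Captures every \code{##INFO}, \code{##FORMAT} and \code{##FILTER}
#' declaration (the metadata that drives all record parsing) and the
#' sample ids from the \code{#CHROM} line.
#'
#' @param lines character vector of header lines (each starting with
#'   \code{##} or \code{#CHROM}).
#' @return a \linkS4class{VcfHeader}.
#' @examples
#' hdr <- parseVcfHeader(c(
#'   "##fileformat=VCFv4.2",
#'   '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"))
#' infoFields(hdr)
#' @export
parseVcfHeader <- function(lines) {
  info <- .emptyFieldFrame()
  format <- .emptyFieldFrame()
  filters <- character(0)
  samples <- character(0)
  chromSeen <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, "##INFO=")) {
      info <- rbind(info, .parseStructuredLine(line, "INFO", i))
    } else if (startsWith(line, "##FORMAT=")) {
      format <- rbind(format, .parseStructuredLine(line, "FORMAT", i))
    } else if (startsWith(line, "##FILTER=")) {
      filters <- c(filters,
                   .parseStructuredLine(line, "FILTER", i)$id)
    } else if (startsWith(line, "#CHROM")) {
      chromSeen <- TRUE
      cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(cols) < 8)
        stop(sprintf("line %d: #CHROM line has %d columns, need >= 8",
                     i, length(cols)))
      if (length(cols) >= 10) samples <- cols[10:length(cols)]
    } else if (!startsWith(line, "##")) {
      stop(sprintf("line %d: header line must start with '##' or '#CHROM': %s",
                   i, line))
    }
  }
  if (!chromSeen)
    stop("header has no #CHROM line")
  if (anyDuplicated(info$id))
    stop(sprintf("duplicate ##INFO declaration for '%s'",
                 info$id[duplicated(info$id)][1]))
  if (anyDuplicated(format$id))
    stop(sprintf("duplicate ##FORMAT declaration for '%s'",
                 format$id[duplicated(format$id)][1]))
  new("VcfHeader", info = info, format = format,
      filters = unique(filters), samples = samples)
}

## Coerce a raw INFO/FORMAT value string to its declared type.  Returns a
## typed vector (comma-split), or the raw string with attribute
## "unparsed" in tolerant mode.
.coerceValue <- function(raw, type, mode, context) {
  parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
  out <- switch(type,
    Integer = suppressWarnings(as.integer(parts)),
    Float = suppressWarnings(as.numeric(parts)),
    String = parts,
    Character = parts,
    parts)
  bad <- is.na(out) & parts != "."
  if (any(bad)) {
    msg <- sprintf("%s: value '%s' is not parsable as %s",
                   context, raw, type)
    if (mode == "strict") stop(msg)
    warning(msg)
    return(structure(parts, unparsed = TRUE))
  }
  out
}

#' Parse one VCF body line into a variant document
#'
#' INFO key=value pairs are parsed to the type declared in the header;
#' comma-separated entries become arrays; bare keys become flags
#' (\code{TRUE}); \code{"."} means the annotation is absent (distinct from
#' zero or empty).  Per-sample FORMAT values are bound positionally to the
#' FORMAT key column; GT and AD get the genotype and allele-depth logic.
#'
#' @param line tab-delimited body line with at least 8 columns.
#' @param header a \linkS4class{VcfHeader}.
#' @param mode \code{"strict"} (undeclared or ill-typed values are errors)
#'   or \code{"tolerant"} (retained as strings with a warning).
#' @param lineNumber line number used in error messages.
#' @return a variant document: a named list with elements \code{chrom},
#'   \code{pos}, \code{id}, \code{ref}, \code{alt} (character vector, one
#'   element after normalization), \code{qual}, \code{filter},
#'   \code{info}, \code{calls} and \code{derived}.
#' @export
parseVcfRecord <- function(line, header, mode = c("tolerant", "strict"),
                           lineNumber = NA_integer_) {
  mode <- match.arg(mode)
  where <- if (is.na(lineNumber)) "record" else
    sprintf("line %d", lineNumber)
  cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 8)
    stop(sprintf("%s: %d columns, a VCF record needs at least 8",
                 where, length(cols)))
  pos <- suppressWarnings(as.integer(cols[2]))
  if (is.na(pos) || pos < 1)
    stop(sprintf("%s: POS '%s' is not a positive integer", where,
                 cols[2]))
  if (!nzchar(cols[4]) || cols[4] == "." || !nzchar(cols[5]))
    stop(sprintf("%s: REF and ALT must be non-empty", where))
  doc <- list(
    chrom = cols[1],
    pos = pos,
    id = if (cols[3] == ".") NA_character_ else cols[3],
    ref = cols[4],
    alt = strsplit(cols[5], ",", fixed = TRUE)[[1]],
    qual = if (cols[6] == ".") NA_real_ else
      suppressWarnings(as.numeric(cols[6])),
    filter = cols[7],
    info = list(),
    calls = list(),
    derived = list()
  )
  if (cols[6] != "." && is.na(doc$qual))
    stop(sprintf("%s: QUAL '%s' is not numeric", where, cols[6]))

  ## --- INFO ---
  if (cols[8] != ".") {
    for (entry in strsplit(cols[8], ";", fixed = TRUE)[[1]]) {
      if (!nzchar(entry)) next
      eq <- regexpr("=", entry, fixed = TRUE)
      key <- if (eq > 0) substr(entry, 1, eq - 1) else entry
      row <- match(key, header@info$id)
      if (is.na(row)) {
        msg <- sprintf("%s: INFO key '%s' is not declared in the header",
                       where, key)
        if (mode == "strict") stop(msg)
        warning(msg)
        type <- if (eq > 0) "String" else "Flag"
      } else type <- header@info$type[row]
      if (type == "Flag") {
        doc$info[[key]] <- TRUE
      } else {
        if (eq < 0)
          stop(sprintf("%s: INFO key '%s' declared %s but has no value",
                       where, key, type))
        raw <- substr(entry, eq + 1, nchar(entry))
        if (raw == "." || !nzchar(raw)) next   # absent annotation
        if (grepl("[\t\n]", raw))
          stop(sprintf("%s: INFO value for '%s' contains tab or newline",
                       where, key))
        doc$info[[key]] <- .coerceValue(raw, type, mode,
          sprintf("%s, INFO '%s'", where, key))
      }
    }
  }

  ## --- FORMAT + samples ---
  if (length(cols) >= 10) {
    keys <- strsplit(cols[9], ":", fixed = TRUE)[[1]]
    undeclared <- setdiff(keys, header@format$id)
    if (length(undeclared)) {
      msg <- sprintf("%s: FORMAT key '%s' is not declared in the header",
                     where, undeclared[1])
      if (mode == "strict") stop(msg) else warning(msg)
    }
    samples <- header@samples
    nSamp <- length(cols) - 9L
    if (nSamp != length(samples))
      stop(sprintf("%s: %d sample columns but header declares %d samples",
                   where, nSamp, length(samples)))
    for (s in seq_len(nSamp)) {
      values <- strsplit(cols[9 + s], ":", fixed = TRUE)[[1]]
      call <- .makeSampleCall(keys, values, nAlt = length(doc$alt))
      ## coerce non-special FORMAT values to their declared types
      for (key in names(call$other)) {
        if (key == "AD") next
        row <- match(key, header@format$id)
        if (!is.na(row))
          call$other[[key]] <- .coerceValue(call$other[[key]],
            header@format$type[row], mode,
            sprintf("%s, FORMAT '%s' sample %s", where, key, samples[s]))
      }
      doc$calls[[samples[s]]] <- call
    }
  }
  .finalizeDoc(doc, header)
}

## Populate derived fields: carrier count/list, numeric FORMAT min/max,
## and the multi-allelic flag.
.finalizeDoc <- function(doc, header) {
  carriers <- sort(names(doc$calls)[vapply(doc$calls,
    function(x) x$altAlleleCount >= 1L, logical(1))])
  doc$derived[["sample_count"]] <- length(carriers)
  doc$derived[["sample_list"]] <- paste(carriers, collapse = ",")
  numFields <- header@format$id[header@format$type %in%
                                  c("Integer", "Float")]
  for (f in setdiff(numFields, "GT")) {
    mm <- summarizeNumericFormat(doc, f, header)
    key <- sprintf("FORMAT.%s", f)
    if (is.null(mm)) {
      doc$derived[[paste0(key, ".min")]] <- NULL
      doc$derived[[paste0(key, ".max")]] <- NULL
    } else {
      doc$derived[[paste0(key, ".min")]] <- mm[1]
      doc$derived[[paste0(key, ".max")]] <- mm[2]
    }
  }
  doc$derived[["multiallelic"]] <- length(doc$alt) > 1
  doc
}

## Open a text connection that transparently handles gzip: gzfile()
## sniffs the magic bytes, so a plain file with a .gz name (or vice
## versa) still reads correctly.
.openVcf <- function(source) {
  if (inherits(source, "connection")) return(source)
  if (!is.character(source) || length(source) != 1)
    stop("source must be a file path or connection")
  if (!file.exists(source))
    stop(sprintf("cannot read '%s': no such file", source))
  gzfile(source, open = "rt")
}

#' Load a VCF file into a VariantDataset
#'
#' Reads a plain or gzip-compressed VCF (compression is detected from the
#' file content, not the extension), parses every record into a typed
#' variant document driven by the header metadata, and populates the
#' derived fields (carrier count and list, per-field sample minima and
#' maxima).  Multi-allelic records are accepted but flagged; pass
#' \code{normalize = TRUE} (or run \code{\link{normalizeMultiallelic}})
#' to split them to one alternate allele per row.
#'
#' @param source file path or text connection.
#' @param mode \code{"tolerant"} (default: undeclared or ill-typed values
#'   are kept as strings with a warning) or \code{"strict"}.
#' @param normalize logical; split multi-allelic records on load.
#' @return a \linkS4class{VariantDataset}.
#' @seealso \code{\link{validateVcf}}, \code{\link{splitMultiallelic}}
#' @export
loadVcf <- function(source, mode = c("tolerant", "strict"),
                    normalize = FALSE) {
  mode <- match.arg(mode)
  con <- .openVcf(source)
  on.exit(close(con))
  headerLines <- character(0)
  header <- NULL
  docs <- list()
  n <- 0L
  lineNo <- 0L
  sawAny <- FALSE
  repeat {
    lines <- readLines(con, n = 4096L)
    if (length(lines) == 0) break
    sawAny <- TRUE
    for (line in lines) {
      lineNo <- lineNo + 1L
      if (is.null(header)) {
        headerLines <- c(headerLines, line)
        if (startsWith(line, "#CHROM"))
          header <- parseVcfHeader(headerLines)
        else if (!startsWith(line, "#"))
          stop(sprintf("line %d: body line before #CHROM header line",
                       lineNo))
      } else {
        if (!nzchar(line)) next
        doc <- parseVcfRecord(line, header, mode, lineNo)
        if (normalize && length(doc$alt) > 1) {
          for (sub in splitMultiallelic(doc, header)) {
            n <- n + 1L
            docs[[n]] <- sub
          }
        } else {
          n <- n + 1L
          docs[[n]] <- doc
        }
      }
    }
  }
  if (!sawAny) stop("empty VCF source")
  if (is.null(header)) stop("header has no #CHROM line")
  new("VariantDataset", header = header, docs = docs,
      ids = seq_len(n), indexes = list())
}

#' Validate a VCF source and report every issue with its line number
#'
#' Checks that the header parses, that every INFO, FORMAT and FILTER key
#' used in the body is declared in the header, that each record parses
#' under the declared types, and that positions are monotone within a
#' chromosome (a warning, not an error).  Nothing is thrown: the issues
#' are the payload, each citing its line number and the offending line.
#'
#' @param source file path or text connection.
#' @return a \linkS4class{ValidationReport}; \code{validationOk(report)}
#'   is \code{TRUE} iff no error-severity issue was found.
#' @export
validateVcf <- function(source) {
  issues <- list()
  addIssue <- function(line, severity, message, text) {
    issues[[length(issues) + 1L]] <<- data.frame(
      line = line, severity = severity, message = message,
      text = substr(text, 1, 200), stringsAsFactors = FALSE)
  }
  con <- tryCatch(.openVcf(source), error = function(e) e)
  if (inherits(con, "error")) {
    addIssue(0L, "error", conditionMessage(con), "")
    return(.mkReport(issues))
  }
  on.exit(close(con))
  headerLines <- character(0)
  header <- NULL
  headerFailed <- FALSE
  lineNo <- 0L
  lastPos <- list()   # chrom -> last POS seen
  sawAny <- FALSE
  repeat {
    lines <- readLines(con, n = 4096L)
    if (length(lines) == 0) break
    sawAny <- TRUE
    for (line in lines) {
      lineNo <- lineNo + 1L
      if (is.null(header) && !headerFailed) {
        headerLines <- c(headerLines, line)
        if (startsWith(line, "#CHROM") || !startsWith(line, "#")) {
          header <- tryCatch(parseVcfHeader(headerLines),
                             error = function(e) e)
          if (inherits(header, "error")) {
            addIssue(lineNo, "error", conditionMessage(header), line)
            header <- NULL
            headerFailed <- TRUE
          }
        }
        if (!is.null(header) || headerFailed) next
      } else if (headerFailed) {
        next
      } else {
        if (!nzchar(line)) next
        doc <- withCallingHandlers(
          tryCatch(parseVcfRecord(line, header, "strict", lineNo),
                   error = function(e) e),
          warning = function(w) {
            addIssue(lineNo, "warning", conditionMessage(w), line)
            invokeRestart("muffleWarning")
          })
        if (inherits(doc, "error")) {
          addIssue(lineNo, "error", conditionMessage(doc), line)
          next
        }
        ## undeclared FILTER codes (PASS and '.' are always legal)
        for (code in strsplit(doc$filter, ";", fixed = TRUE)[[1]]) {
          if (!code %in% c("PASS", ".") &&
              !code %in% header@filters)
            addIssue(lineNo, "error",
                     sprintf("FILTER code '%s' is not declared in the header",
                             code), line)
        }
        prev <- lastPos[[doc$chrom]]
        if (!is.null(prev) && doc$pos < prev)
          addIssue(lineNo, "warning",
                   sprintf("position %d is before %d on %s (unsorted input)",
                           doc$pos, prev, doc$chrom), line)
        lastPos[[doc$chrom]] <- doc$pos
      }
    }
  }
  if (!sawAny) addIssue(0L, "error", "empty VCF source", "")
  else if (is.null(header) && !headerFailed)
    addIssue(lineNo, "error", "header has no #CHROM line", "")
  .mkReport(issues)
}

.mkReport <- function(issues) {
  df <- if (length(issues)) do.call(rbind, issues) else
    data.frame(line = integer(0), severity = character(0),
               message = character(0), text = character(0),
               stringsAsFactors = FALSE)
  new("ValidationReport", ok = !any(df$severity == "error"), issues = df)
}

## Slice a typed INFO/FORMAT value for alternate allele k of nAlt, per
## its declared Number: A = one value per alternate, R = reference plus
## one per alternate, G/./fixed = copied unchanged.
.sliceValue <- function(value, number, k, nAlt, field) {
  if (identical(number, "A")) {
    if (length(value) != nAlt)
      stop(sprintf(
        "field '%s' declared Number=A has %d values for %d alternates",
        field, length(value), nAlt))
    value[k]
  } else if (identical(number, "R")) {
    if (length(value) != nAlt + 1L)
      stop(sprintf(
        "field '%s' declared Number=R has %d values for %d alternates",
        field, length(value), nAlt))
    value[c(1L, k + 1L)]
  } else value
}

#' Split a multi-allelic variant document into one document per alternate
#'
#' Returns one document per ALT allele.  INFO and FORMAT fields declared
#' per-alternate (\code{Number=A}) are sliced to the matching element and
#' \code{Number=R} fields to reference plus the matching element; shared
#' fields are copied.  The AD field is rebuilt so each output carries the
#' reference depth and that allele's depth.  GT allele indices are
#' remapped so the retained alternate becomes index 1; other alternates
#' are mapped to index 2 and still count as non-reference for zygosity
#' (a \code{"1/2"} sample remains a carrier in both outputs).
#'
#' @param doc a variant document with k >= 1 alternate alleles.
#' @param header the dataset's \linkS4class{VcfHeader}.
#' @return list of k single-alternate documents (a singleton list, the
#'   document unchanged, when k = 1).
#' @export
splitMultiallelic <- function(doc, header) {
  nAlt <- length(doc$alt)
  if (nAlt <= 1) return(list(doc))
  lapply(seq_len(nAlt), function(k) {
    out <- doc
    out$alt <- doc$alt[k]
    for (key in names(doc$info)) {
      row <- match(key, header@info$id)
      number <- if (is.na(row)) "." else header@info$number[row]
      out$info[[key]] <- .sliceValue(doc$info[[key]], number, k, nAlt,
                                     key)
    }
    for (sid in names(doc$calls)) {
      call <- doc$calls[[sid]]
      ## remap GT: 0 stays, index k+1 -> 1, other alternates -> 2
      if (!is.na(call$gt) && call$gt != ".") {
        seps <- strsplit(gsub("[0-9.]+", "", call$gt), "")[[1]]
        tokens <- strsplit(call$gt, "[/|]")[[1]]
        ## ALT allele k has GT index k
        newTokens <- vapply(tokens, function(t) {
          if (t == "." || t == "0") t
          else if (as.integer(t) == k) "1"
          else "2"
        }, character(1))
        gt <- newTokens[1]
        if (length(newTokens) > 1)
          for (j in 2:length(newTokens))
            gt <- paste0(gt, seps[j - 1], newTokens[j])
        call$gt <- gt
        cls <- classifyGenotype(gt)
        call$zygosity <- cls$zygosity
        call$altAlleleCount <- cls$altAlleleCount
      }
      ## AD: reference depth plus this allele's depth
      rawAd <- call$other[["AD"]]
      if (!is.null(rawAd) && rawAd != ".") {
        parts <- strsplit(rawAd, ",", fixed = TRUE)[[1]]
        if (length(parts) == nAlt + 1L) {
          newAd <- paste(parts[c(1L, k + 1L)], collapse = ",")
          call$other[["AD"]] <- newAd
          ad <- parseAlleleDepth(newAd)
          call$refDepth <- ad$refDepth
          call$altDepth <- ad$altDepth
        }
      }
      ## slice other per-alternate FORMAT values
      for (key in setdiff(names(call$other), "AD")) {
        row <- match(key, header@format$id)
        number <- if (is.na(row)) "." else header@format$number[row]
        call$other[[key]] <- .sliceValue(call$other[[key]], number, k,
                                         nAlt, key)
      }
      out$calls[[sid]] <- call
    }
    .finalizeDoc(out, header)
  })
}

#' Normalize every multi-allelic record of a dataset
#'
#' Applies \code{\link{splitMultiallelic}} to each flagged document,
#' assigning fresh stable ids to the split rows (file order preserved).
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @return a normalized \linkS4class{VariantDataset}; indexes are dropped
#'   (rebuild them after normalization).
#' @export
normalizeMultiallelic <- function(ds) {
  out <- list()
  for (doc in ds@docs)
    for (sub in splitMultiallelic(doc, ds@header))
      out[[length(out) + 1L]] <- sub
  new("VariantDataset", header = ds@header, docs = out,
      ids = seq_along(out), indexes = list())
}
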