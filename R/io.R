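# Readers and writers for every external format the pipeline touches:
# quantification tables (native and MaxQuant-proteinGroups-like dialects),
# GMT gene-set collections, identifier maps, result tables (TSV/JSON) and the
# scatter-browser JSON export.

.dialects <- list(
  native = list(
    protein_id = "protein_id", gene_symbol = "gene_symbol",
    ratio_hl = "ratio_hl", n_peptides = "n_peptides_ratio",
    reverse = NULL, contaminant = NULL
  ),
  maxquant = list(
    protein_id = "Protein IDs", gene_symbol = "Gene names",
    ratio_hl = "Ratio H/L normalized", n_peptides = "Ratio H/L count",
    reverse = "Reverse", contaminant = "Potential contaminant"
  )
)

#' Read a protein quantification table
#'
#' Ingests one run of one fraction. Rows are filtered the way a SILAC ratio
#' table is conventionally cleaned before analysis: reverse-decoy and
#' contaminant-flagged rows are dropped when the dialect exposes those flags,
#' rows with a missing or non-positive normalized H/L ratio are dropped (their
#' log-ratio is undefined), and rows whose ratio rests on fewer than
#' `min_peptides` peptides are dropped (the two-peptide minimum — one unique
#' plus one razor — required for a reliable SILAC ratio). Each row is counted
#' under the first filter it fails; the counts are attached as a load report.
#'
#' Protein groups listing several accessions (separated by `;`) are
#' represented by their first accession; multi-symbol gene names likewise.
#'
#' @param path TSV file.
#' @param dialect `"native"` (columns `protein_id`, `gene_symbol`, `ratio_hl`,
#'   `n_peptides_ratio`) or `"maxquant"` (proteinGroups-like columns
#'   `Protein IDs`, `Gene names`, `Ratio H/L normalized`, `Ratio H/L count`,
#'   `Reverse`, `Potential contaminant`).
#' @param orientation which label carried the control cells in this run:
#'   `"control-heavy"` or `"control-light"`. Never inferred from the data —
#'   the sign of every downstream index depends on it.
#' @param run_label `"exp1"` or `"exp2"`.
#' @param fraction `"cytosol"` or `"chromatin"`.
#' @param min_peptides minimum peptide count backing a retained ratio.
#' @return data.frame with columns `protein_id`, `gene_symbol`, `ratio_hl`,
#'   `n_peptides_ratio`, `run_label`, `fraction`; attributes `orientation` and
#'   `load_report` (list with `rows_in`, `rows_retained` and per-reason
#'   exclusion counts that sum exactly to `rows_in`).
#' @export
read_protein_quant <- function(path, dialect = c("native", "maxquant"),
                               orientation = c("control-heavy", "control-light"),
                               run_label = c("exp1", "exp2"),
                               fraction = c("cytosol", "chromatin"),
                               min_peptides = 2L) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  run_label <- match.arg(run_label)
  fraction <- match.arg(fraction)
  if (!file.exists(path)) stop(sprintf("cannot read quant table: '%s'", path), call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  cols <- .dialects[[dialect]]
  for (nm in c("protein_id", "ratio_hl", "n_peptides")) {
    if (!cols[[nm]] %in% names(raw))
      stop(sprintf("quant table '%s' is missing mandatory column '%s'", path, cols[[nm]]),
           call. = FALSE)
  }
  n_in <- nrow(raw)
  excl <- c(decoy = 0L, contaminant = 0L, nonpositive_ratio = 0L, low_peptide_count = 0L)
  alive <- rep(TRUE, n_in)
  flag_plus <- function(col) {
    if (is.null(col) || !col %in% names(raw)) return(rep(FALSE, n_in))
    !is.na(raw[[col]]) & raw[[col]] == "+"
  }
  hit <- alive & flag_plus(cols$reverse)
  excl["decoy"] <- sum(hit); alive <- alive & !hit
  hit <- alive & flag_plus(cols$contaminant)
  excl["contaminant"] <- sum(hit); alive <- alive & !hit
  ratio <- suppressWarnings(as.numeric(raw[[cols$ratio_hl]]))
  hit <- alive & (is.na(ratio) | ratio <= 0)
  excl["nonpositive_ratio"] <- sum(hit); alive <- alive & !hit
  npep <- suppressWarnings(as.integer(raw[[cols$n_peptides]]))
  hit <- alive & (is.na(npep) | npep < min_peptides)
  excl["low_peptide_count"] <- sum(hit); alive <- alive & !hit

  first_token <- function(x) sub(";.*$", "", as.character(x))
  gene <- if (!is.null(cols$gene_symbol) && cols$gene_symbol %in% names(raw)) {
    first_token(raw[[cols$gene_symbol]])
  } else rep("", n_in)
  gene[is.na(gene)] <- ""
  out <- data.frame(
    protein_id = first_token(raw[[cols$protein_id]])[alive],
    gene_symbol = gene[alive],
    ratio_hl = ratio[alive],
    n_peptides_ratio = npep[alive],
    run_label = run_label, fraction = fraction,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$protein_id))
    stop(sprintf("quant table '%s' has duplicated protein_id within one run", path),
         call. = FALSE)
  attr(out, "orientation") <- orientation
  attr(out, "load_report") <- list(rows_in = n_in, rows_retained = nrow(out),
                                   excluded = as.list(excl))
  out
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a set are de-duplicated with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read GMT file: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)), call. = FALSE)
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicated members de-duplicated", fields[1]),
              call. = FALSE)
      members <- unique(members)
    }
    if (fields[1] %in% names(sets))
      stop(sprintf("GMT file has duplicated set name '%s'", fields[1]), call. = FALSE)
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-to-gene identifier map
#'
#' Two-column TSV (`protein_id`, `gene_symbol`). The mapping is total:
#' identifiers absent from the map pass through unchanged (see
#' [apply_id_map()]).
#'
#' @param path TSV file with a header.
#' @return named character vector, `protein_id -> gene_symbol`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read id map: '%s'", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("id map must have two columns", call. = FALSE)
  key <- as.character(tab[[1]]); val <- as.character(tab[[2]])
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k) length(unique(val[key == k])) > 1L,
                       logical(1))
    if (any(conflict))
      stop(sprintf("id map has conflicting duplicate key '%s'",
                   names(conflict)[conflict][1]), call. = FALSE)
    keep <- !dup
    key <- key[keep]; val <- val[keep]
  }
  stats::setNames(val, key)
}

#' Apply an identifier map, passing unmapped identifiers through
#'
#' @param ids character vector of identifiers.
#' @param map named vector from [read_id_map()]; `NULL` is the identity.
#' @return character vector with an `n_unmapped` attribute counting the
#'   identifiers that passed through unchanged.
#' @export
apply_id_map <- function(ids, map = NULL) {
  if (is.null(map) || length(map) == 0L) {
    return(structure(ids, n_unmapped = length(ids)))
  }
  hit <- ids %in% names(map)
  out <- ids
  out[hit] <- unname(map[ids[hit]])
  structure(out, n_unmapped = sum(!hit))
}

#' Write a result table to TSV or JSON
#'
#' Numeric fields are serialized at full double precision so that a write/read
#' round trip reproduces the values (to within one unit in the last place).
#'
#' @param records data.frame.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @param comments optional character vector written as `# `-prefixed header
#'   lines (TSV only); used by the pipeline runners to record the seed.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "json"), comments = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste("#", comments), con)
  rec <- records
  for (j in seq_along(rec)) {
    if (is.double(rec[[j]])) rec[[j]] <- sprintf("%.17g", rec[[j]])
  }
  utils::write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file to read.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- jsonlite::fromJSON(path)
    if (length(out) == 0L) out <- data.frame()
    return(out)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Export the scatter-browser JSON payload
#'
#' One object per gene with its cytosol and chromatin mPAI coordinates, the
#' quadrant call, and the gene sets it belongs to — the payload behind a
#' searchable, zoomable scatter plot of the two-fraction comparison.
#'
#' @param quadrants data.frame from [join_fractions()].
#' @param sets gene-set collection (named list) used to annotate memberships;
#'   `NULL` for no annotation.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_browser_json <- function(quadrants, sets = NULL, path) {
  membership <- function(g) {
    if (is.null(sets)) return(character(0))
    names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
  }
  payload <- lapply(seq_len(nrow(quadrants)), function(i) {
    list(gene = quadrants$gene_symbol[i],
         mpai_cytosol = quadrants$mpai_cytosol[i],
         mpai_chromatin = quadrants$mpai_chromatin[i],
         quadrant = quadrants$quadrant[i],
         significant = quadrants$significant[i],
         sets = as.list(membership(quadrants$gene_symbol[i])))
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
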