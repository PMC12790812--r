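# Readers/writers for FASTA, FASTQ, TSV tables and the run config.

#' Read a (multi-record) FASTA file into a tibble
#'
#' Sequences are upper-cased and line wrapping is removed. Record ids must
#' be unique and sequences non-empty.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `description`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble::tibble(id = character(0), seq = character(0),
                          description = character(0)))
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  description <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(x))
  if (any(id == "")) stop("FASTA record with empty id", call. = FALSE)
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate FASTA ids: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  empty <- id[nchar(seqs) == 0]
  if (length(empty) > 0) {
    stop(sprintf("empty sequence for record(s): %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  .check_iupac(seqs, what = sprintf("FASTA file %s", path))
  tibble::tibble(id = unname(id), seq = unname(seqs),
                 description = unname(description))
}

#' Write a tibble of sequences to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  x <- Biostrings::BStringSet(seqs$seq)
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  names(x) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(nrow(seqs))
}

#' Write simulated reads to FASTQ (Phred+33)
#'
#' Read names follow the PacBio CCS convention `<movie>/<zmw>/ccs`; the
#' header comment carries provenance tags (`sample=`, `genome=`, `asv=`,
#' `np=`) so reads stay traceable to their source templates while names
#' remain vendor-conformant.
#'
#' @param reads Tibble with at least `read_id`, `seq`, `qual` (quality as a
#'   Phred+33 string of the same length as `seq`); provenance columns
#'   `sample_id`, `genome_id`, `asv_id`, `np` are encoded in the comment
#'   field when present.
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0) {
    file.create(path)
    return(invisible(0L))
  }
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad) > 0) {
    stop(sprintf("seq/qual length mismatch for read(s): %s",
                 paste(reads$read_id[head(bad, 5)], collapse = ", ")),
         call. = FALSE)
  }
  comment <- character(nrow(reads))
  for (col in c("sample_id", "genome_id", "asv_id", "np", "template_id")) {
    if (col %in% names(reads)) {
      tag <- c(sample_id = "sample", genome_id = "genome", asv_id = "asv",
               np = "np", template_id = "template")[[col]]
      comment <- paste0(comment, " ", tag, "=", reads[[col]])
    }
  }
  header <- paste0("@", reads$read_id, comment)
  lines <- as.vector(rbind(header, reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(nrow(reads))
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to a FASTQ (Phred+33) file.
#' @return Tibble with columns `read_id`, `seq`, `qual` plus any provenance
#'   tags (`key=value` pairs) found in the header comment.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble::tibble(read_id = character(0), seq = character(0),
                          qual = character(0)))
  }
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: not 4 lines/record")
  header <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  out <- tibble::tibble(
    read_id = sub("\\s.*$", "", header),
    seq = toupper(lines[seq(2, length(lines), by = 4)]),
    qual = lines[seq(4, length(lines), by = 4)]
  )
  comment <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  if (any(nzchar(comment))) {
    tags <- stringr::str_match_all(comment, "(\\w+)=(\\S+)")
    keys <- unique(unlist(lapply(tags, function(m) m[, 2])))
    for (k in keys) {
      out[[k]] <- vapply(tags, function(m) {
        v <- m[m[, 2] == k, 3]
        if (length(v) == 0) NA_character_ else v[[1]]
      }, character(1))
    }
    if ("np" %in% names(out)) out$np <- as.integer(out$np)
  }
  out
}

#' Read a dual-barcode table
#'
#' @param path TSV with header `sample_id`, `fwd_barcode`, `rev_barcode`.
#' @return Tibble with those columns, validated (non-empty, unique pairs).
#' @export
read_barcodes <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_barcodes(tbl)
}

#' @noRd
validate_barcodes <- function(tbl) {
  stopifnot(all(c("sample_id", "fwd_barcode", "rev_barcode") %in% names(tbl)))
  tbl$fwd_barcode <- toupper(tbl$fwd_barcode)
  tbl$rev_barcode <- toupper(tbl$rev_barcode)
  if (any(!nzchar(tbl$fwd_barcode)) || any(!nzchar(tbl$rev_barcode))) {
    stop("empty barcode sequence", call. = FALSE)
  }
  .check_iupac(c(tbl$fwd_barcode, tbl$rev_barcode), "barcode table")
  pair <- paste(tbl$fwd_barcode, tbl$rev_barcode)
  if (anyDuplicated(pair)) {
    stop("duplicate (fwd, rev) barcode pair across samples", call. = FALSE)
  }
  if (anyDuplicated(tbl$sample_id)) stop("duplicate sample_id", call. = FALSE)
  tibble::as_tibble(tbl)
}

#' Read / write a pass-number histogram table
#'
#' @param path TSV with header `np`, `count`.
#' @return Tibble with integer `np` and numeric `count`.
#' @export
read_np_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "id", progress = FALSE)
  stopifnot(all(c("np", "count") %in% names(tbl)))
  tibble::as_tibble(tbl)
}

#' @rdname read_np_table
#' @param tbl Tibble with columns `np`, `count`.
#' @export
write_np_table <- function(tbl, path) {
  readr::write_tsv(tbl[, c("np", "count")], path)
  invisible(path)
}

#' Write the ground-truth sidecar table for a simulated read set
#'
#' Emitted alongside the FASTQ because downstream tools may strip header
#' comments.
#'
#' @param reads Reads tibble from [simulate_reads()] / [run_pipeline()].
#' @param path Output TSV path.
#' @export
write_ground_truth <- function(reads, path) {
  cols <- intersect(c("read_id", "sample_id", "genome_id", "asv_id",
                      "template_id", "np", "template_len"), names(reads))
  readr::write_tsv(reads[, cols], path)
  invisible(path)
}

#' Read / write a run configuration (YAML or JSON)
#'
#' The on-disk config mirrors the fields of [run_config()]; the file format
#' is chosen by extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Config file path.
#' @return A validated `hifisim_config` object.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, lst)
}

#' @rdname read_run_config
#' @param config A `hifisim_config` object.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$error_ratio <- as.numeric(lst$error_ratio)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}
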