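# Reading/writing FASTA and the delimited annotation & capsid tables.
# FASTA parsing goes through Biostrings; validation specific to this pipeline
# (alphabet, unique ids, stop-mark stripping) is layered on top.

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased, a single trailing stop mark `*` is stripped, and
#' every residue must belong to [aa_alphabet()]. Annotation columns (`group`,
#' `functional_class`, `family`) are created empty for later joining with
#' [read_annotation_table()].
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Tibble with columns `id`, `sequence`, `group`, `functional_class`,
#'   `family`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "KKDDE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*$", lines))
  if (length(body) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), sequence = character(),
                          group = character(), functional_class = character(),
                          family = character()))
  }
  if (!startsWith(lines[body[1]], ">")) {
    stop("malformed FASTA: sequence before any '>' header at line ",
         body[1], call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(path)
  id <- sub("\\s.*$", "", names(seqs))
  sequence <- unname(toupper(as.character(seqs)))
  sequence <- sub("\\*$", "", sequence)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(sequence) == 0L)) {
    stop("zero-length sequence for id(s): ",
         paste(id[nchar(sequence) == 0L], collapse = ", "), call. = FALSE)
  }
  ok <- aa_alphabet()
  for (i in seq_along(sequence)) {
    res <- unique(strsplit(sequence[i], "", fixed = TRUE)[[1]])
    bad <- setdiff(res, ok)
    if (length(bad) > 0L) {
      stop("record '", id[i], "' contains residue(s) outside the accepted ",
           "alphabet: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  tibble::tibble(id = id, sequence = sequence,
                 group = NA_character_, functional_class = NA_character_,
                 family = NA_character_)
}

#' Write protein records to FASTA
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# detect comma vs tab dialect from the header line
.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read a per-protein annotation table
#'
#' Delimited text (comma or tab, auto-detected from the header) with
#' mandatory columns `id`, `group`, `functional_class`, `family`. Unknown
#' columns are ignored; empty optional fields are kept as empty strings.
#'
#' @param path Path to the table.
#' @return Tibble keyed by `id` with the three annotation columns.
#' @export
read_annotation_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- .read_delim_auto(path)
  needed <- c("id", "group", "functional_class", "family")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(
    dplyr::select(tab, dplyr::all_of(needed)),
    dplyr::across(dplyr::everything(),
                  ~ dplyr::coalesce(as.character(.x), "")))
  if (any(out$id == "")) stop("annotation table has empty id(s)",
                              call. = FALSE)
  if (anyDuplicated(out$id)) {
    stop("annotation table has duplicate id(s): ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Join annotations onto protein records
#'
#' Exact accession match; records without a matching annotation keep empty
#' fields (they are retained for scanning but excluded from group-wise
#' statistics).
#'
#' @param records Tibble from [read_fasta()].
#' @param annotation Tibble from [read_annotation_table()].
#' @return `records` with `group`, `functional_class`, `family` filled in
#'   where an annotation row exists.
#' @export
annotate_records <- function(records, annotation) {
  dplyr::left_join(
    dplyr::select(records, -"group", -"functional_class", -"family"),
    annotation, by = "id")
}

.genome_types <- c("ssDNA", "dsDNA", "+ssRNA", "dsRNA")

# "L1:360;L2:72" -> tibble(protein, copies)
.parse_components <- function(x, row) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) == 0L) {
    stop("capsid table row ", row, ": no components", call. = FALSE)
  }
  kv <- strsplit(trimws(parts), ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("capsid table row ", row, ": components must be 'protein:copies' ",
         "pairs separated by ';'", call. = FALSE)
  }
  protein <- vapply(kv, `[[`, "", 1L)
  copies <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  if (anyNA(copies) || any(copies < 1) || any(copies != round(copies))) {
    stop("capsid table row ", row, ": copy numbers must be integers >= 1",
         call. = FALSE)
  }
  tibble::tibble(protein = protein, copies = as.integer(copies))
}

.parse_segments <- function(x, row) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  seg <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(seg) == 0L || anyNA(seg) || any(seg < 1) ||
      any(seg != round(seg))) {
    stop("capsid table row ", row, ": genome segments must be integer ",
         "lengths >= 1 separated by ';'", call. = FALSE)
  }
  as.integer(seg)
}

#' Read a capsid stoichiometry table
#'
#' Delimited text (comma or tab) with columns `virus`, `family`,
#' `genome_type` (one of ssDNA, dsDNA, +ssRNA, dsRNA), `t_number`,
#' `components` (semicolon-separated `protein:copies` pairs),
#' `genome_segments` (semicolon-separated lengths, nt for single-stranded
#' genomes, bp for double-stranded), `host_class` (`eukaryotic` or
#' `bacteriophage`) and `motor_packaged` (logical). An optional `q_max`
#' column of precomputed per-component charges (semicolon-separated, aligned
#' with `components`) is honoured if present.
#'
#' @param path Path to the table.
#' @return Tibble with one row per virus; `components` and `genome_segments`
#'   are list columns.
#' @export
read_capsid_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- .read_delim_auto(path)
  needed <- c("virus", "family", "genome_type", "t_number", "components",
              "genome_segments", "host_class", "motor_packaged")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop("capsid table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(tab)
  comp <- vector("list", n)
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    if (!(tab$genome_type[i] %in% .genome_types)) {
      stop("capsid table row ", i, ": unknown genome_type '",
           tab$genome_type[i], "' (expected one of ",
           paste(.genome_types, collapse = ", "), ")", call. = FALSE)
    }
    comp[[i]] <- .parse_components(as.character(tab$components[i]), i)
    segs[[i]] <- .parse_segments(as.character(tab$genome_segments[i]), i)
    if ("q_max" %in% names(tab) && !is.na(tab$q_max[i])) {
      qm <- suppressWarnings(
        as.numeric(strsplit(as.character(tab$q_max[i]), ";")[[1]]))
      if (length(qm) != nrow(comp[[i]]) || anyNA(qm)) {
        stop("capsid table row ", i, ": q_max column must hold one numeric ",
             "value per component", call. = FALSE)
      }
      comp[[i]]$q_max <- qm
    }
  }
  tibble::tibble(
    virus = as.character(tab$virus), family = as.character(tab$family),
    genome_type = as.character(tab$genome_type),
    t_number = as.character(tab$t_number),
    components = comp, genome_segments = segs,
    host_class = as.character(tab$host_class),
    motor_packaged = as.logical(tab$motor_packaged))
}
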