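#' Construct a PSSM matrix object
#'
#' A position-specific scoring matrix couples an L-residue protein
#' sequence with an L x 20 matrix of integer log-odds substitution
#' scores, one column per standard amino acid in the canonical
#' [AA_ORDER]. Entry (i, j) scores replacement of the residue at
#' position i by amino acid j during iterative profile search.
#'
#' @param scores Integer L x 20 matrix of log-odds scores. Entries must
#'   be whole numbers with absolute value at most 32 (anything larger
#'   indicates a parsing problem, real profiles stay well inside this).
#' @param residues Character scalar: the protein sequence, one letter per
#'   matrix row. The 20 standard letters plus `X` are accepted;
#'   lowercase is normalized to uppercase.
#' @param id Sample identifier.
#' @return Object of class `pssm_matrix` with elements `scores`
#'   (integer matrix, columns named by [AA_ORDER]), `residues` and `id`.
#' @examples
#' m <- pssm_matrix(matrix(0L, 3, 20), "ACD", id = "toy")
#' dim(m$scores)
#' @export
pssm_matrix <- function(scores, residues, id = "") {
  scores <- as.matrix(scores)
  residues <- toupper(as.character(residues)[1])
  if (ncol(scores) != 20L) {
    stop_validation("a PSSM must have exactly 20 columns, got ", ncol(scores))
  }
  if (nrow(scores) != nchar(residues)) {
    stop_validation("row count (", nrow(scores), ") != sequence length (",
                    nchar(residues), ")")
  }
  if (nrow(scores) < 1L) stop_validation("empty PSSM")
  if (anyNA(scores) || any(scores != round(scores))) {
    stop_validation("PSSM log-odds must be integers")
  }
  if (any(abs(scores) > 32)) {
    stop_validation("PSSM entry out of the plausible log-odds band |v| <= 32")
  }
  bad <- setdiff(strsplit(residues, "")[[1]], c(AA_ORDER, "X"))
  if (length(bad)) {
    stop_validation("illegal residue letter(s): ",
                    paste(unique(bad), collapse = ", "))
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(NULL, AA_ORDER)
  structure(list(scores = scores, residues = residues, id = id),
            class = "pssm_matrix")
}

#' @export
print.pssm_matrix <- function(x, ...) {
  cat("PSSM '", x$id, "': L = ", nrow(x$scores), ", 20 columns (",
      paste(AA_ORDER[1:5], collapse = " "), " ...)\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the text layout produced by `psiblast -out_ascii_pssm` (profiles
#' are typically generated with three PSI-BLAST iterations at an E-value
#' of 0.001 against a large sequence database; running the search itself
#' is out of scope here). The file has three header lines, then one body
#' row per residue: position index, residue letter, 20 integer log-odds,
#' 20 weighted observed percentages, and optionally two information
#' columns. Only the log-odds block is retained; the footer with
#' K/Lambda statistics is ignored when present.
#'
#' @param path Path to the ASCII PSSM file.
#' @return A [pssm_matrix()] holding the 20 log-odds columns; the `id` is
#'   the file name without extension.
#' @seealso [write_pssm()] for the inverse operation.
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop_parse("missing PSSM header in ", path)
  hdr <- lines[3]
  if (length(gregexpr("[A-Z]", hdr)[[1]]) < 40L) {
    stop_parse("missing PSSM column header (line 3) in ", path)
  }
  body <- lines[-(1:3)]
  end <- which(!grepl("^\\s*\\d+\\s+[A-Za-z]", body))
  if (length(end)) body <- body[seq_len(end[1] - 1L)]
  if (!length(body)) stop_parse("no PSSM body rows in ", path)

  rows <- strsplit(trimws(body), "\\s+")
  res <- character(length(rows))
  mat <- matrix(0L, length(rows), 20L)
  for (k in seq_along(rows)) {
    f <- rows[[k]]
    nums <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(nums) || length(nums) < 40L) {
      stop_parse("row ", k, " of ", path, ": expected 40 numeric score ",
                 "fields, got ", sum(!is.na(nums)))
    }
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx) || idx != k) {
      stop_parse("inconsistent row count in ", path, ": body row ", k,
                 " is labelled position ", f[1])
    }
    lo <- nums[1:20]
    if (any(lo != round(lo))) {
      stop_parse("row ", k, " of ", path, ": non-integer log-odds value")
    }
    res[k] <- toupper(f[2])
    mat[k, ] <- as.integer(lo)
  }
  pssm_matrix(mat, paste(res, collapse = ""),
              id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a PSSM matrix as a PSI-BLAST ASCII file
#'
#' Emits the `-out_ascii_pssm` dialect accepted by [parse_pssm()]. The
#' weighted-percentage block is zero-filled (only the log-odds block is
#' modelled); a minimal K/Lambda footer is appended. Round-trips are
#' exact on the log-odds block.
#'
#' @param m A [pssm_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(m, path) {
  stopifnot(inherits(m, "pssm_matrix"))
  res <- strsplit(m$residues, "")[[1]]
  hdr <- c("",
           paste("Last position-specific scoring matrix computed, weighted",
                 "observed percentages rounded down, information per position,",
                 "and relative weight of gapless real matches to pseudocounts"),
           paste0("           ", paste(sprintf("%3s", AA_ORDER), collapse = ""),
                  " ", paste(sprintf("%3s", AA_ORDER), collapse = "")))
  body <- vapply(seq_len(nrow(m$scores)), function(i) {
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%3d", m$scores[i, ]), collapse = ""), " ",
           paste(sprintf("%3d", integer(20L)), collapse = ""),
           sprintf("  %5.2f %9.2f", 0, 0))
  }, "")
  foot <- c("", "                      K         Lambda",
            "Standard Ungapped    0.1367     0.3179",
            "Standard Gapped      0.0410     0.2670")
  out <- tryCatch(writeLines(c(hdr, body, foot), path),
                  error = function(e) stop_io("cannot write ", path, ": ",
                                              conditionMessage(e)))
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are read with Biostrings and then validated against the
#' package alphabet: the 20 standard amino acids plus `X`. Record ids are
#' truncated at the first whitespace; wrapped sequence lines are
#' concatenated.
#'
#' @param path FASTA file path.
#' @return List of protein sequence records, each a list with elements
#'   `id` and `residues` (uppercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  if (file.size(path) == 0L) stop_empty("empty FASTA file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop_empty("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- unique(unlist(lapply(seqs, function(s) {
    setdiff(strsplit(s, "")[[1]], c(AA_ORDER, "X"))
  })))
  if (length(bad)) {
    stop_validation("illegal sequence letter(s): ", paste(bad, collapse = ", "))
  }
  mapply(function(i, s) list(id = i, residues = s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Assemble a labelled PSSM dataset
#'
#' @param pssms Named list of [pssm_matrix()] objects (names are sample
#'   ids; unnamed lists use each matrix's own `id`).
#' @param positives,negatives Character vectors of sample ids for the
#'   DNA-binding (positive) and non-binding (negative) class. The two
#'   sets must be disjoint and jointly covered by `pssms`.
#' @return Object of class `pssm_dataset`.
#' @export
pssm_dataset <- function(pssms, positives, negatives) {
  if (is.null(names(pssms)) || any(!nzchar(names(pssms)))) {
    names(pssms) <- vapply(pssms, function(m) m$id, "")
  }
  if (length(intersect(positives, negatives))) {
    stop_validation("positive and negative id sets overlap: ",
                    paste(intersect(positives, negatives), collapse = ", "))
  }
  missing <- setdiff(c(positives, negatives), names(pssms))
  if (length(missing)) {
    stop_validation("ids without a PSSM: ", paste(missing, collapse = ", "))
  }
  structure(list(pssms = pssms, positives = positives, negatives = negatives),
            class = "pssm_dataset")
}

#' @export
print.pssm_dataset <- function(x, ...) {
  cat("PSSM dataset:", length(x$positives), "positives,",
      length(x$negatives), "negatives\n")
  invisible(x)
}

#' Write a dataset as a directory of PSSM files plus a label table
#'
#' Creates one ASCII PSSM file `<id>.pssm` per sample and a two-column
#' tab-separated `labels.tsv` (`id`, `label` with 1 = DNA-binding),
#' i.e. exactly the external input format of the pipeline.
#'
#' @param ds A [pssm_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the path of the label table.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "pssm_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- c(ds$positives, ds$negatives)
  for (id in ids) write_pssm(ds$pssms[[id]], file.path(dir, paste0(id, ".pssm")))
  lab <- data.frame(id = ids,
                    label = c(rep(1L, length(ds$positives)),
                              rep(0L, length(ds$negatives))))
  path <- file.path(dir, "labels.tsv")
  utils::write.table(lab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path Tab-separated file with columns `id` and `label` (0/1).
#' @return Data frame with character `id` and integer `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  lab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer"))
  if (!all(c("id", "label") %in% names(lab))) {
    stop_parse("label table must have columns 'id' and 'label'")
  }
  if (!all(lab$label %in% c(0L, 1L))) {
    stop_validation("labels must be 0 or 1")
  }
  lab
}

#' Read a directory of PSSM files into a dataset
#'
#' @param dir Directory containing `*.pssm` files.
#' @param labels Optional data frame from [read_labels()]; when given,
#'   the dataset's positive/negative split follows it, otherwise all
#'   samples are placed in the positive slot with a zero-length negative
#'   set (prediction-only use).
#' @param skip_bad If `TRUE`, unparseable files are skipped with a
#'   warning instead of aborting the run.
#' @return A [pssm_dataset()].
#' @export
read_pssm_dir <- function(dir, labels = NULL, skip_bad = FALSE) {
  files <- list.files(dir, pattern = "\\.pssm$", full.names = TRUE)
  if (!length(files)) stop_empty("no .pssm files in ", dir)
  pssms <- list()
  for (f in files) {
    m <- tryCatch(parse_pssm(f), error = function(e) {
      if (skip_bad) {
        warning("skipping ", f, ": ", conditionMessage(e), call. = FALSE)
        NULL
      } else stop(e)
    })
    if (!is.null(m)) pssms[[m$id]] <- m
  }
  if (!length(pssms)) stop_empty("no parseable .pssm files in ", dir)
  if (is.null(labels)) {
    pssm_dataset(pssms, positives = names(pssms), negatives = character())
  } else {
    keep <- labels$id %in% names(pssms)
    labels <- labels[keep, , drop = FALSE]
    pssm_dataset(pssms[labels$id],
                 positives = labels$id[labels$label == 1L],
                 negatives = labels$id[labels$label == 0L])
  }
}
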