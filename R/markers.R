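#' Parse HMMER per-target tabular output (tblout)
#'
#' Reads the whitespace-delimited target-per-line format written by
#' `hmmsearch --tblout`. Comment lines (`#`) are skipped. The query name
#' (profile model) is mapped to a marker via `cutoffs`; hits are compared
#' against the model's trusted bit-score cutoff where one is provided,
#' otherwise against an E-value fallback at presence-calling time.
#'
#' @param path Path to a tblout file.
#' @param genome_id Genome identifier for all hits in the file; default
#'   is the file name without extension (the one-genome-per-scan layout).
#' @param cutoffs Optional data frame with columns `model`,
#'   `trusted_cutoff` (bits) and optionally `marker`; when `marker` is
#'   present it maps model names onto the marker vocabulary, otherwise
#'   the query name is used as the marker directly.
#' @return Data frame of class `"hmm_hits"` with columns `genome_id`,
#'   `marker`, `model`, `score`, `evalue`, `trusted_cutoff`,
#'   `meets_cutoff`.
#' @export
read_hmm_tblout <- function(path, genome_id = NULL, cutoffs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data_lines)) {
    out <- data.frame(genome_id = character(), marker = character(),
                      model = character(), score = numeric(),
                      evalue = numeric(), trusted_cutoff = numeric(),
                      meets_cutoff = logical())
    class(out) <- c("hmm_hits", class(out))
    return(out)
  }
  rows <- lapply(seq_along(data_lines), function(i) {
    f <- strsplit(trimws(data_lines[i]), "\\s+")[[1]]
    if (length(f) < 6L)
      stop(sprintf("malformed tblout line %d: fewer than 6 fields",
                   which(lines == data_lines[i])[1]))
    ev <- suppressWarnings(as.numeric(f[5]))
    sc <- suppressWarnings(as.numeric(f[6]))
    if (is.na(ev) || is.na(sc))
      stop(sprintf("malformed tblout line %d: non-numeric E-value/score",
                   which(lines == data_lines[i])[1]))
    data.frame(target = f[1], model = f[3], evalue = ev, score = sc)
  })
  hits <- do.call(rbind, rows)
  if (!is.null(cutoffs)) {
    idx <- match(hits$model, cutoffs$model)
    hits$trusted_cutoff <- cutoffs$trusted_cutoff[idx]
    hits$marker <- if ("marker" %in% names(cutoffs))
      ifelse(is.na(idx), hits$model, as.character(cutoffs$marker[idx]))
    else hits$model
  } else {
    hits$trusted_cutoff <- NA_real_
    hits$marker <- hits$model
  }
  out <- data.frame(genome_id = genome_id, marker = hits$marker,
                    model = hits$model, score = hits$score,
                    evalue = hits$evalue,
                    trusted_cutoff = hits$trusted_cutoff)
  out$meets_cutoff <- ifelse(is.na(out$trusted_cutoff),
                             out$evalue <= 1e-5,
                             out$score >= out$trusted_cutoff)
  class(out) <- c("hmm_hits", class(out))
  out
}

#' Marker presence/absence matrix from HMM hits
#'
#' A marker is called present in a genome when at least one hit meets its
#' model's trusted bit-score cutoff (or, for models without a curated
#' cutoff, has E-value at or below `evalue_fallback`). The best
#' qualifying hit per cell is kept as provenance.
#'
#' @param hits One or several `hmm_hits` data frames (rbind-compatible).
#' @param genomes Character vector of genome ids defining the rows; ids
#'   without any hit yield all-absent rows (with a warning), so scanned
#'   but marker-free genomes are retained.
#' @param markers Marker vocabulary defining the columns. Default
#'   [MARKER_SET].
#' @param evalue_fallback E-value threshold for models without a trusted
#'   cutoff. Default 1e-5.
#' @return Logical `marker_matrix` (genomes x markers) with attribute
#'   `"provenance"`: data frame of the best qualifying hit per present
#'   cell.
#' @export
presence_matrix <- function(hits, genomes = NULL, markers = MARKER_SET,
                            evalue_fallback = 1e-5) {
  if (is.list(hits) && !is.data.frame(hits)) hits <- do.call(rbind, hits)
  if (is.null(genomes)) genomes <- unique(hits$genome_id)
  if (!length(genomes)) stop("no genomes given and no hits to infer them from")
  m <- matrix(FALSE, length(genomes), length(markers),
              dimnames = list(genomes, markers))
  qual <- hits[ifelse(is.na(hits$trusted_cutoff),
                      hits$evalue <= evalue_fallback,
                      hits$score >= hits$trusted_cutoff), , drop = FALSE]
  qual <- qual[qual$genome_id %in% genomes & qual$marker %in% markers, ,
               drop = FALSE]
  prov <- NULL
  if (nrow(qual)) {
    qual <- qual[order(qual$genome_id, qual$marker, -qual$score), , drop = FALSE]
    best <- qual[!duplicated(qual[c("genome_id", "marker")]), , drop = FALSE]
    m[cbind(match(best$genome_id, genomes), match(best$marker, markers))] <- TRUE
    prov <- best
  }
  empty <- genomes[!genomes %in% hits$genome_id]
  if (length(empty))
    warning("genome(s) with zero scanned markers: ",
            paste(empty, collapse = ", "))
  structure(m, class = c("marker_matrix", "matrix", "array"),
            provenance = prov)
}

#' Aerobic anoxygenic phototroph (AAPB) classification rule
#'
#' A genome is called (putative) AAPB when it possesses the three
#' dark-operative protochlorophyllide oxidoreductase subunits (BchB,
#' BchL, BchN), a pheophytin-quinone type II reaction center (PufL and
#' PufM), at least one magnesium-protoporphyrin monomethyl ester
#' oxidative cyclase (AcsF or BchE), and lacks the Calvin-cycle pair --
#' by default, lacks RuBisCO (large chain) and/or phosphoribulokinase,
#' i.e. only a genome carrying both is disqualified. Set
#' `rubisco_mode = "both_absent"` for the strict reading requiring both
#' to be missing.
#'
#' @param markers A named logical vector (one genome) or a logical
#'   `marker_matrix` (genomes x markers); names/columns must include
#'   BchB, BchL, BchN, PufL, PufM, AcsF, BchE, RuBisCO_large, PRK.
#' @param rubisco_mode `"either_absent"` (default) or `"both_absent"`.
#' @return For a single genome, a list of class `"aapb_call"`:
#'   `is_aapb`, `reasons` (named logical per clause). For a matrix, a
#'   data frame with `genome_id`, `is_aapb` and one column per clause.
#' @export
call_aapb <- function(markers, rubisco_mode = c("either_absent", "both_absent")) {
  rubisco_mode <- match.arg(rubisco_mode)
  need <- c("BchB", "BchL", "BchN", "PufL", "PufM", "AcsF", "BchE",
            "RuBisCO_large", "PRK")
  if (is.matrix(markers)) {
    if (!all(need %in% colnames(markers)))
      stop("marker matrix is missing required columns")
    calls <- lapply(seq_len(nrow(markers)), function(i)
      call_aapb(markers[i, ], rubisco_mode))
    out <- data.frame(
      genome_id = rownames(markers) %||% as.character(seq_len(nrow(markers))),
      is_aapb = vapply(calls, `[[`, logical(1), "is_aapb"))
    reasons <- do.call(rbind, lapply(calls, function(cl) cl$reasons))
    cbind(out, as.data.frame(reasons))
  } else {
    if (!all(need %in% names(markers)))
      stop("marker vector is missing required entries: ",
           paste(setdiff(need, names(markers)), collapse = ", "))
    m <- as.logical(markers[need])
    names(m) <- need
    reasons <- c(
      dpor_complete = unname(m["BchB"] && m["BchL"] && m["BchN"]),
      rc_type_ii = unname(m["PufL"] && m["PufM"]),
      oxidative_cyclase = unname(m["AcsF"] || m["BchE"]),
      lacks_calvin = if (rubisco_mode == "either_absent")
        unname(!m["RuBisCO_large"] || !m["PRK"])
      else unname(!m["RuBisCO_large"] && !m["PRK"]))
    structure(list(is_aapb = all(reasons), reasons = reasons),
              class = "aapb_call")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.aapb_call <- function(x, ...) {
  cat(sprintf("<aapb_call: %s [%s]>\n",
              if (x$is_aapb) "AAPB" else "not AAPB",
              paste(names(x$reasons)[!x$reasons], collapse = ", ")))
  invisible(x)
}
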