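#' Promoter region container
#'
#' Bundles a promoter DNA sequence with the 0-based positions of its CpG
#' dinucleotides. All interval arithmetic in the package is 0-based and
#' half-open; 1-based CpG display labels are only attached in human-readable
#' reports.
#'
#' @param name Region identifier (e.g. a transcript promoter name).
#' @param sequence DNA string over `A,C,G,T,N` (lower case accepted).
#' @param strand Strand of the associated transcript relative to the given
#'   sequence, `"+"` or `"-"`. CpG methylation is treated as strand-symmetric,
#'   so CpG sites are always indexed by the position of the C on the supplied
#'   orientation; `strand` is annotation only.
#' @param tss_offset Optional 0-based offset of the transcription start within
#'   the sequence.
#'
#' @return An object of class `promoter_region`: a list with elements `name`,
#'   `sequence`, `cpg_positions` (0-based integer vector), `strand`,
#'   `tss_offset`.
#' @examples
#' promoter_region("prom", "ACGTCGA")$cpg_positions
#' @export
promoter_region <- function(name, sequence, strand = "+", tss_offset = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) > 0 && grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  strand <- match.arg(strand, c("+", "-"))
  if (!is.null(tss_offset)) {
    stopifnot(tss_offset >= 0, tss_offset < nchar(sequence))
    tss_offset <- as.integer(tss_offset)
  }
  structure(
    list(
      name = name,
      sequence = sequence,
      cpg_positions = find_cpg_sites(sequence),
      strand = strand,
      tss_offset = tss_offset
    ),
    class = "promoter_region"
  )
}

#' @export
print.promoter_region <- function(x, ...) {
  cat(
    "<promoter_region> ", x$name, ": ", nchar(x$sequence), " bp, ",
    length(x$cpg_positions), " CpG sites, strand ", x$strand, "\n",
    sep = ""
  )
  invisible(x)
}

#' Locate CpG dinucleotides in a sequence
#'
#' @param sequence DNA string over `A,C,G,T,N`.
#' @return Integer vector of 0-based positions `p` with
#'   `substr(sequence, p + 1, p + 2) == "CG"`, strictly increasing. `N` never
#'   matches. An empty sequence yields an empty vector.
#' @examples
#' find_cpg_sites("CGCG") # 0, 2
#' @export
find_cpg_sites <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (is.na(sequence) || nchar(sequence) < 2) return(integer(0))
  m <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Detect CpG islands with the sliding-window criterion
#'
#' A CpG island is conventionally a CpG-dense stretch of at least 200 nt with
#' elevated GC content and CpG observed/expected ratio. Every window of
#' `window` nt is tested for GC fraction >= `gc_min` and CpG obs/exp >=
#' `obs_exp_min` (observed CpG count divided by `n_C * n_G / window`);
#' positions covered by any passing window are merged into maximal intervals,
#' and intervals at least `min_len` nt long are reported.
#'
#' The defaults (`window = 200`, `gc_min = 0.5`, `obs_exp_min = 0.6`,
#' `min_len = 200`) are the standard Gardiner-Garden-style rule. A stricter
#' literal reading of "> 60% GC" is available via `gc_min = 0.6`.
#'
#' @param sequence DNA string.
#' @param min_len Minimum island length (nt).
#' @param gc_min Minimum GC fraction per window.
#' @param obs_exp_min Minimum CpG observed/expected ratio per window.
#' @param window Window size (nt); must not exceed `min_len`.
#' @return A tibble with columns `start`, `end` (0-based, half-open), sorted
#'   and non-overlapping. Sequences shorter than `window` yield zero rows.
#' @examples
#' find_cpg_islands(strrep("CG", 100))
#' @export
find_cpg_islands <- function(sequence, min_len = 200, gc_min = 0.5,
                             obs_exp_min = 0.6, window = 200) {
  stopifnot(min_len > 0, window > 0, window <= min_len)
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  empty <- tibble::tibble(start = integer(0), end = integer(0))
  if (L < window) return(empty)

  base <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_c <- base == "C"
  is_g <- base == "G"
  # CpG start indicator at position i (1-based), length L - 1 padded to L
  is_cpg <- c(is_c[-L] & is_g[-1L], FALSE)

  csum <- function(x) c(0, cumsum(x))
  cc <- csum(is_c); gg <- csum(is_g); pp <- csum(is_cpg)
  starts <- seq_len(L - window + 1L) # 1-based window starts
  n_c <- cc[starts + window] - cc[starts]
  n_g <- gg[starts + window] - gg[starts]
  # CpGs fully inside the window: start positions in [start, start + window - 2]
  n_cpg <- pp[starts + window - 1L] - pp[starts]
  gc <- (n_c + n_g) / window
  expected <- n_c * n_g / window
  oe <- ifelse(expected > 0, n_cpg / expected, 0)
  pass <- gc >= gc_min & oe >= obs_exp_min

  if (!any(pass)) return(empty)
  covered <- logical(L)
  for (s in starts[pass]) covered[s:(s + window - 1L)] <- TRUE
  r <- rle(covered)
  ends1 <- cumsum(r$lengths)
  starts1 <- ends1 - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(
    start = as.integer(starts1[keep] - 1L),
    end = as.integer(ends1[keep])
  )
}

# readr treats plain strings as paths; mark embedded-newline input as literal
as_tsv_input <- function(file) {
  if (length(file) == 1L && is.character(file) && grepl("\n", file)) I(file) else file
}

#' Compute delta-Ct
#'
#' `dCt = Ct(target) - Ct(reference)`; lower delta-Ct corresponds to higher
#' target abundance. Missing Ct values propagate to missing delta-Ct.
#'
#' @param ct_target,ct_reference Numeric vectors of cycle thresholds.
#' @return Numeric vector of delta-Ct values.
#' @examples
#' compute_dct(25, 20)
#' @export
compute_dct <- function(ct_target, ct_reference) {
  ct_target - ct_reference
}

#' Read a per-CpG methylation table
#'
#' Expects a tab-separated file with a header row: a `sample` column, an
#' optional `replicate` column (assumed 1 when absent), and one column per
#' CpG site holding percent methylation in \[0, 100\] (`NA` for missing,
#' e.g. pyrosequencing dropouts).
#'
#' @param file Path to a TSV file, or a literal string containing the table
#'   (anything with a newline is treated as content).
#' @param region Optional [promoter_region()]; when supplied, the number of
#'   CpG columns must equal the number of CpG sites in the region.
#' @return A long tibble with columns `sample`, `replicate`, `cpg` (1-based
#'   display label, integer), `percent`, carrying the region name in the
#'   `region` attribute. Sample and CpG order follow the file.
#' @export
read_methylation_table <- function(file, region = NULL) {
  raw <- readr::read_tsv(as_tsv_input(file),
                         col_types = readr::cols(.default = readr::col_character()),
                         na = c("NA", ""), progress = FALSE)
  if (!"sample" %in% names(raw)) {
    stop("methylation table must have a 'sample' column", call. = FALSE)
  }
  if (!"replicate" %in% names(raw)) raw$replicate <- "1"
  cpg_cols <- setdiff(names(raw), c("sample", "replicate"))
  if (length(cpg_cols) == 0) stop("no CpG columns found", call. = FALSE)
  if (anyDuplicated(raw[c("sample", "replicate")])) {
    d <- raw[duplicated(raw[c("sample", "replicate")]), c("sample", "replicate")]
    stop(
      "duplicate (sample, replicate) rows: ",
      paste(d$sample, d$replicate, sep = "/", collapse = ", "),
      call. = FALSE
    )
  }
  long <- tidyr::pivot_longer(raw, dplyr::all_of(cpg_cols),
                              names_to = "cpg_label", values_to = "percent")
  long$percent <- suppressWarnings(as.numeric(long$percent))
  long$cpg <- match(long$cpg_label, cpg_cols)
  bad <- !is.na(long$percent) & (long$percent < 0 | long$percent > 100)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(
      sprintf(
        "methylation percent outside [0,100]: value %s at sample '%s', column '%s'",
        format(long$percent[i]), long$sample[i], long$cpg_label[i]
      ),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    sample = long$sample,
    replicate = as.integer(long$replicate),
    cpg = as.integer(long$cpg),
    percent = long$percent
  )
  out <- dplyr::arrange(out, match(sample, unique(raw$sample)), replicate, cpg)
  if (!is.null(region)) {
    if (length(region$cpg_positions) != length(cpg_cols)) {
      stop(
        sprintf(
          "region '%s' has %d CpG sites but table has %d CpG columns",
          region$name, length(region$cpg_positions), length(cpg_cols)
        ),
        call. = FALSE
      )
    }
    attr(out, "region") <- region$name
  }
  attr(out, "cpg_labels") <- cpg_cols
  out
}

#' Write a methylation table in the wide TSV layout
#'
#' Inverse of [read_methylation_table()]: one row per (sample, replicate),
#' one column per CpG.
#'
#' @param meth Long methylation tibble (`sample`, `replicate`, `cpg`,
#'   `percent`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_methylation_table <- function(meth, file) {
  wide <- tidyr::pivot_wider(
    meth,
    id_cols = c("sample", "replicate"),
    names_from = "cpg", names_prefix = "CpG_", values_from = "percent"
  )
  readr::write_tsv(wide, file, na = "NA", progress = FALSE)
  invisible(file)
}

#' Read an expression (delta-Ct) table
#'
#' Tab-separated, one row per (sample, replicate): a `sample` column, an
#' optional `replicate` column, and either one delta-Ct column per transcript,
#' or paired raw columns `<transcript>_ct` and `<transcript>_ref_ct` from
#' which delta-Ct is derived with [compute_dct()].
#'
#' @param file Path or literal TSV content.
#' @return Long tibble with columns `sample`, `replicate`, `transcript`,
#'   `dct`.
#' @export
read_expression_table <- function(file) {
  raw <- readr::read_tsv(as_tsv_input(file), col_types = readr::cols(
    sample = readr::col_character(), .default = readr::col_double()
  ), na = c("NA", ""), progress = FALSE)
  if (!"sample" %in% names(raw)) {
    stop("expression table must have a 'sample' column", call. = FALSE)
  }
  if (!"replicate" %in% names(raw)) raw$replicate <- 1
  value_cols <- setdiff(names(raw), c("sample", "replicate"))
  ct_cols <- grep("_ct$", value_cols, value = TRUE)
  ct_cols <- setdiff(ct_cols, grep("_ref_ct$", value_cols, value = TRUE))
  if (length(ct_cols) > 0) {
    for (tc in ct_cols) {
      tr <- sub("_ct$", "", tc)
      ref <- paste0(tr, "_ref_ct")
      if (!ref %in% names(raw)) {
        stop("missing reference column '", ref, "' for '", tc, "'", call. = FALSE)
      }
      raw[[tr]] <- compute_dct(raw[[tc]], raw[[ref]])
      raw[[tc]] <- NULL
      raw[[ref]] <- NULL
    }
    value_cols <- setdiff(names(raw), c("sample", "replicate"))
  }
  out <- tidyr::pivot_longer(raw, dplyr::all_of(value_cols),
                             names_to = "transcript", values_to = "dct")
  out$replicate <- as.integer(out$replicate)
  out[c("sample", "replicate", "transcript", "dct")]
}

#' Read a qMSP table
#'
#' Tab-separated with columns `sample`, `group`, `ct_target`, `ct_reference`.
#' Groups follow the cohort vocabulary `case_tissue`, `case_plasma`,
#' `control_smoker`, `control_nonsmoker`, plus the assay controls `C_plus`
#' (fully methylated DNA) and `C_minus` (fully unmethylated DNA). Missing
#' `ct_target` encodes no amplification of the methylation-specific amplicon;
#' missing `ct_reference` invalidates the sample.
#'
#' @param file Path or literal TSV content.
#' @return Tibble with the input columns plus derived `dct`.
#' @export
read_qmsp_table <- function(file) {
  raw <- readr::read_tsv(as_tsv_input(file), col_types = readr::cols(
    sample = readr::col_character(), group = readr::col_character(),
    ct_target = readr::col_double(), ct_reference = readr::col_double()
  ), na = c("NA", ""), progress = FALSE)
  need <- c("sample", "group", "ct_target", "ct_reference")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("qMSP table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  raw$dct <- compute_dct(raw$ct_target, raw$ct_reference)
  raw
}

#' Read JASPAR-format position frequency matrices
#'
#' Accepts both circulating JASPAR dialects: bracketed base rows
#' (`A [ 4 0 ]`) and bare 4-row count matrices. Records start with a `>`
#' header carrying the motif accession and (optionally) name; the four rows
#' must be in A, C, G, T order when unlabelled, and are matched by label when
#' labelled.
#'
#' @param file Path or literal PFM text (anything containing a newline).
#' @return A list of PFM records, each a list with `motif_id`, `motif_name`,
#'   `counts` (4 x width numeric matrix, rows named A,C,G,T), `width`.
#' @export
read_jaspar_pfm <- function(file) {
  txt <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(paste(file, collapse = "\n"), "\n", fixed = TRUE))
  }
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  if (length(txt) == 0) return(list())
  heads <- grep("^>", txt)
  if (length(heads) == 0) stop("no '>' header lines found", call. = FALSE)
  bounds <- c(heads, length(txt) + 1L)
  purrr::map(seq_along(heads), function(i) {
    header <- sub("^>\\s*", "", txt[heads[i]])
    parts <- strsplit(header, "[\t ]+")[[1]]
    body <- txt[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4L) {
      stop(
        "record '", parts[1], "': expected 4 base rows, found ", length(body),
        call. = FALSE
      )
    }
    labelled <- grepl("^[ACGTacgt]\\b", body)
    rows <- lapply(seq_along(body), function(j) {
      line <- body[j]
      label <- NA_character_
      if (labelled[j]) {
        label <- toupper(substr(line, 1, 1))
        line <- sub("^[ACGTacgt]", "", line)
      } else if (grepl("^[A-Za-z]", line)) {
        stop("record '", parts[1], "': unknown base row label in '", body[j], "'",
             call. = FALSE)
      }
      line <- gsub("[][]", " ", line)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "[\t ]+")[[1]]))
      if (anyNA(vals)) {
        stop("record '", parts[1], "': non-numeric counts in '", body[j], "'",
             call. = FALSE)
      }
      list(label = label, vals = vals)
    })
    labels <- vapply(rows, `[[`, character(1), "label")
    if (all(!is.na(labels))) {
      if (!setequal(labels, c("A", "C", "G", "T"))) {
        stop("record '", parts[1], "': base row labels must be A,C,G,T", call. = FALSE)
      }
      rows <- rows[match(c("A", "C", "G", "T"), labels)]
    } else if (any(!is.na(labels))) {
      stop("record '", parts[1], "': mix of labelled and unlabelled rows", call. = FALSE)
    }
    widths <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(widths)) != 1L) {
      stop(
        "record '", parts[1], "': base rows have unequal widths (",
        paste(widths, collapse = ", "), ")",
        call. = FALSE
      )
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) {
      stop("record '", parts[1], "': negative counts", call. = FALSE)
    }
    if (any(colSums(counts) == 0)) {
      stop("record '", parts[1], "': a column has no positive count", call. = FALSE)
    }
    list(
      motif_id = parts[1],
      motif_name = if (length(parts) > 1) paste(parts[-1], collapse = " ") else parts[1],
      counts = counts,
      width = ncol(counts)
    )
  })
}

#' Read promoter sequences from FASTA
#'
#' @param file FASTA path.
#' @param strand Strand annotation applied to all records.
#' @return A named list of [promoter_region()] objects, in file order.
#' @export
read_promoter_fasta <- function(file, strand = "+") {
  seqs <- Biostrings::readDNAStringSet(file)
  out <- purrr::map2(
    names(seqs), as.character(seqs),
    function(nm, sq) promoter_region(sub("\\s.*$", "", nm), sq, strand = strand)
  )
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Write promoter sequences to FASTA
#'
#' @param regions A [promoter_region()] or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_promoter_fasta <- function(regions, file) {
  if (inherits(regions, "promoter_region")) regions <- list(regions)
  ss <- Biostrings::DNAStringSet(vapply(regions, `[[`, character(1), "sequence"))
  names(ss) <- vapply(regions, `[[`, character(1), "name")
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Serialize a report table
#'
#' Writes a tibble as TSV (tab-delimited, `NA` for missing) or JSON with a
#' deterministic column order; [read_report()] round-trips either format.
#' List columns (e.g. contained CpG labels on motif hits) are flattened to
#' comma-separated strings in TSV.
#'
#' @param rows A data frame of report rows.
#' @param file Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_report <- function(rows, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  rows <- tibble::as_tibble(rows)
  if (format == "tsv") {
    flat <- dplyr::mutate(rows, dplyr::across(
      dplyr::where(is.list),
      ~ vapply(.x, function(v) paste(v, collapse = ","), character(1))
    ))
    readr::write_tsv(flat, file, na = "NA", progress = FALSE)
  } else {
    jsonlite::write_json(rows, file, dataframe = "rows", na = "null", digits = NA)
  }
  invisible(file)
}

#' Read a report table written by [write_report()]
#'
#' @param file Path to a `.tsv` or `.json` report.
#' @param format Format; inferred from the extension by default.
#' @return A tibble.
#' @export
read_report <- function(file, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", file)) "json" else "tsv"
  }
  if (format == "json") {
    tibble::as_tibble(jsonlite::read_json(file, simplifyVector = TRUE))
  } else {
    readr::read_tsv(file, na = "NA", show_col_types = FALSE, progress = FALSE)
  }
}

#' Write motif hits as BED6
#'
#' One line per hit: `chrom` = region name, 0-based half-open interval,
#' `name` = motif id, `score` = `-10 * log10(p)` capped at 1000, strand.
#'
#' @param hits Hit tibble from [scan_sequence()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_hits_bed <- function(hits, file) {
  score <- pmin(round(-10 * log10(pmax(hits$p, 1e-300))), 1000)
  bed <- tibble::tibble(
    chrom = hits$region, start = hits$start, end = hits$end,
    name = hits$motif_id, score = score, strand = hits$strand
  )
  readr::write_tsv(bed, file, col_names = FALSE, progress = FALSE)
  invisible(file)
}
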