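#' Construct a validated time-course differential-expression table
#'
#' The central input container: one row per (gene, gene type, time point)
#' holding the log2 fold change and adjusted p-value of that gene at that
#' time point, plus an ordered time-point axis. Invariants enforced here:
#' unique (gene, type, time point) triples, every time point on the declared
#' axis, `padj` in \[0, 1\], finite `log2fc`.
#'
#' @param records data.frame with columns `gene`, `gene_type`
#'   ("miRNA"/"mRNA"), `time_point`, `log2fc`, `padj`.
#' @param time_points character vector giving the ordered time-point axis.
#' @return object of class `TimeCourseDE` (a data.frame with a
#'   `time_points` attribute).
#' @export
time_course_de <- function(records, time_points) {
  stopifnot(is.data.frame(records))
  need <- c("gene", "gene_type", "time_point", "log2fc", "padj")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  records <- records[, need]
  records$gene <- as.character(records$gene)
  records$gene_type <- as.character(records$gene_type)
  records$time_point <- as.character(records$time_point)
  if (!all(records$gene_type %in% c("miRNA", "mRNA"))) {
    stop("gene_type must be 'miRNA' or 'mRNA'")
  }
  bad_tp <- setdiff(unique(records$time_point), time_points)
  if (length(bad_tp)) {
    stop("time point(s) not on the declared axis: ",
         paste(bad_tp, collapse = ", "))
  }
  if (!is.numeric(records$log2fc) || any(!is.finite(records$log2fc))) {
    stop("log2fc must be finite numeric")
  }
  if (!is.numeric(records$padj) || any(is.na(records$padj)) ||
      any(records$padj < 0 | records$padj > 1)) {
    stop("padj must be numeric in [0, 1]")
  }
  key <- paste(records$gene, records$gene_type, records$time_point, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop("duplicate (gene, gene_type, time_point) record(s), e.g. ",
         dup$gene[1], " / ", dup$time_point[1])
  }
  # canonical row order: gene type, gene, then axis position
  ord <- order(records$gene_type, records$gene,
               match(records$time_point, time_points))
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(records, time_points = as.character(time_points),
            class = c("TimeCourseDE", "data.frame"))
}

#' @export
print.TimeCourseDE <- function(x, ...) {
  tps <- attr(x, "time_points")
  cat("TimeCourseDE: ", length(unique(x$gene[x$gene_type == "miRNA"])),
      " miRNAs, ", length(unique(x$gene[x$gene_type == "mRNA"])),
      " mRNAs over ", length(tps), " time points (",
      paste(tps, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Time-point axis of a time-course object
#' @param de a `TimeCourseDE`.
#' @return character vector of ordered time-point labels.
#' @export
de_time_points <- function(de) attr(de, "time_points")

#' Read a per-time-point differential-expression table
#'
#' Accepts the two tab-separated dialects used throughout the package:
#' wide (one row per gene; columns `gene`, then `log2fc_<tp>` and
#' `padj_<tp>` per time point) and long (columns `gene`, `time_point`,
#' `log2fc`, `padj`). Validation is strict: a missing per-time-point column,
#' a non-numeric cell, or a duplicated gene label is a hard error.
#'
#' @param path file path of the tab-separated table.
#' @param gene_type "miRNA" or "mRNA" (the table holds one type).
#' @param time_points ordered time-point labels to keep, in this order.
#' @return a [time_course_de()] object restricted to `time_points`.
#' @export
read_de_table <- function(path, gene_type = c("miRNA", "mRNA"), time_points) {
  gene_type <- match.arg(gene_type)
  if (!file.exists(path)) stop("DE table not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!"gene" %in% names(tab)) stop("DE table must have a 'gene' column: ", path)

  as_num <- function(v, colname) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !(is.na(v) | v == "NA" | v == ""))
    if (length(bad)) {
      stop("non-numeric value in column '", colname, "' at data row ",
           bad[1], ": '", v[bad[1]], "'")
    }
    out
  }

  long_cols <- c("time_point", "log2fc", "padj")
  if (all(long_cols %in% names(tab))) {
    rec <- data.frame(gene = tab$gene, gene_type = gene_type,
                      time_point = tab$time_point,
                      log2fc = as_num(tab$log2fc, "log2fc"),
                      padj = as_num(tab$padj, "padj"),
                      stringsAsFactors = FALSE)
    rec <- rec[rec$time_point %in% time_points, , drop = FALSE]
  } else {
    if (anyDuplicated(tab$gene)) {
      stop("duplicate gene label in DE table: ",
           tab$gene[duplicated(tab$gene)][1])
    }
    recs <- vector("list", length(time_points))
    for (i in seq_along(time_points)) {
      tp <- time_points[i]
      lc <- paste0("log2fc_", tp)
      pc <- paste0("padj_", tp)
      if (!lc %in% names(tab)) stop("missing column '", lc, "' in ", path)
      if (!pc %in% names(tab)) stop("missing column '", pc, "' in ", path)
      recs[[i]] <- data.frame(gene = tab$gene, gene_type = gene_type,
                              time_point = tp,
                              log2fc = as_num(tab[[lc]], lc),
                              padj = as_num(tab[[pc]], pc),
                              stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, recs)
  }
  time_course_de(rec, time_points)
}

#' Write a time-course table in the wide dialect
#'
#' One row per gene of the requested type, columns `gene` then
#' `log2fc_<tp>` / `padj_<tp>` per time point; values printed at 15
#' significant digits so a write/read cycle reproduces the records.
#'
#' @param de a `TimeCourseDE`.
#' @param path output file path.
#' @param gene_type which gene type to write.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path, gene_type = c("miRNA", "mRNA")) {
  gene_type <- match.arg(gene_type)
  tps <- de_time_points(de)
  sub <- de[de$gene_type == gene_type, , drop = FALSE]
  genes <- sort(unique(sub$gene))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (tp in tps) {
    at <- sub[sub$time_point == tp, , drop = FALSE]
    idx <- match(genes, at$gene)
    out[[paste0("log2fc_", tp)]] <- at$log2fc[idx]
    out[[paste0("padj_", tp)]] <- at$padj[idx]
  }
  write_tsv_det(out, path, digits = 15)
}

#' Merge miRNA and mRNA time-course tables
#' @param ... `TimeCourseDE` objects sharing one time-point axis.
#' @return merged `TimeCourseDE`.
#' @export
bind_de <- function(...) {
  parts <- list(...)
  tps <- de_time_points(parts[[1]])
  for (p in parts[-1]) {
    if (!identical(de_time_points(p), tps)) {
      stop("all tables must share the same time-point axis")
    }
  }
  time_course_de(do.call(rbind, lapply(parts, as.data.frame)), tps)
}

#' Filter genes for per-time-point significance
#'
#' Each gene is filtered at each time point independently of every other
#' time point: it enters the set for time point t iff its adjusted p-value
#' at t is <= `alpha` (inclusive boundary). Combined mode pools miRNA and
#' mRNA labels into one set per time point; separate mode keeps one set per
#' (time point, gene type).
#'
#' @param de a `TimeCourseDE`.
#' @param mode "combined" or "separate".
#' @param alpha adjusted-p threshold in (0, 1\]; default 0.05.
#' @return object of class `SignificantSets`: a list with `sets` (named list
#'   of gene-label vectors), `keys` (data.frame of key, time_point,
#'   gene_type), `mode`, `alpha`, `time_points`.
#' @export
filter_significant <- function(de, mode = c("combined", "separate"),
                               alpha = 0.05) {
  mode <- match.arg(mode)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1)) {
    stop("alpha must be a single value in (0, 1]")
  }
  tps <- de_time_points(de)
  sets <- list()
  keys <- list()
  if (mode == "combined") {
    for (tp in tps) {
      hit <- de[de$time_point == tp & de$padj <= alpha, , drop = FALSE]
      sets[[tp]] <- sort(unique(hit$gene))
      keys[[tp]] <- data.frame(key = tp, time_point = tp, gene_type = NA_character_,
                               stringsAsFactors = FALSE)
    }
  } else {
    for (tp in tps) {
      for (gt in c("miRNA", "mRNA")) {
        k <- paste(tp, gt, sep = "|")
        hit <- de[de$time_point == tp & de$gene_type == gt & de$padj <= alpha,
                  , drop = FALSE]
        sets[[k]] <- sort(unique(hit$gene))
        keys[[k]] <- data.frame(key = k, time_point = tp, gene_type = gt,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (all(lengths(sets) == 0)) {
    warning("no gene passes padj <= ", alpha, " at any time point")
  }
  structure(list(sets = sets, keys = do.call(rbind, keys), mode = mode,
                 alpha = alpha, time_points = tps),
            class = "SignificantSets")
}

#' @export
print.SignificantSets <- function(x, ...) {
  cat("SignificantSets (", x$mode, " mode, alpha = ", x$alpha, "): ",
      length(x$sets), " sets, sizes ",
      paste(lengths(x$sets), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Map input gene labels to entrez/ensembl identifiers
#'
#' Reads a tab-separated mapping table with columns `input_label`, `entrez`,
#' `ensembl` and returns a total map over every distinct (gene, gene type)
#' in the time-course data. Labels with no mapping row are retained with
#' absent (NA) entrez/ensembl. The adjusted label is the input label itself,
#' which is unique per gene type by construction; in particular the -3p/-5p
#' suffix of mature miRNA names is preserved even when both arms map to the
#' same entrez/ensembl gene, so downstream networks can keep the two arms
#' apart. mRNA labels sharing one entrez are both retained with a warning;
#' enrichment de-duplicates by mapped identifier.
#'
#' @param de a `TimeCourseDE`.
#' @param map_table path of the tab-separated mapping table.
#' @return object of class `IDMap`: data.frame with columns `input_label`,
#'   `gene_type`, `entrez`, `ensembl`, `adjusted_label`.
#' @export
map_ids <- function(de, map_table) {
  if (!file.exists(map_table)) stop("ID map table not found: ", map_table)
  map <- tryCatch(
    read.delim(map_table, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("unreadable ID map table: ", conditionMessage(e))
  )
  need <- c("input_label", "entrez", "ensembl")
  if (!all(need %in% names(map))) {
    stop("ID map table must have columns: ", paste(need, collapse = ", "))
  }
  blank_to_na <- function(v) ifelse(is.na(v) | v == "", NA_character_, v)
  map$entrez <- blank_to_na(map$entrez)
  map$ensembl <- blank_to_na(map$ensembl)

  uniq <- unique(as.data.frame(de)[, c("gene", "gene_type")])
  uniq <- uniq[order(uniq$gene_type, uniq$gene), , drop = FALSE]
  idx <- match(uniq$gene, map$input_label)
  out <- data.frame(input_label = uniq$gene, gene_type = uniq$gene_type,
                    entrez = map$entrez[idx], ensembl = map$ensembl[idx],
                    adjusted_label = uniq$gene, stringsAsFactors = FALSE)
  rownames(out) <- NULL

  mr <- out[out$gene_type == "mRNA" & !is.na(out$entrez), , drop = FALSE]
  dup <- unique(mr$entrez[duplicated(mr$entrez)])
  if (length(dup)) {
    warning("mRNA labels sharing one entrez ID (kept; enrichment ",
            "de-duplicates): ", paste(dup, collapse = ", "))
  }
  structure(out, class = c("IDMap", "data.frame"))
}

# translate gene labels into the declared namespace; unmapped labels drop out
translate_labels <- function(labels, ids, namespace = c("entrez", "ensembl")) {
  if (is.null(ids)) return(unique(labels))
  namespace <- match.arg(namespace)
  idx <- match(labels, ids$input_label)
  out <- ids[[namespace]][idx]
  unique(out[!is.na(out)])
}
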