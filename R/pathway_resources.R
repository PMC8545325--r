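#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name<TAB>id<TAB>member1<TAB>member2...`. Members are de-duplicated per
#' line. The identifier namespace (entrez or ensembl) is declared by the
#' caller, never sniffed; a line mixing all-digit and ENS-prefixed tokens is
#' rejected as mixed-namespace.
#'
#' @param path GMT file path.
#' @param namespace "entrez" or "ensembl" — namespace of the member IDs.
#' @return object of class `PathwaySet`: list with `id`, `name`,
#'   `members` (named list keyed by pathway ID), `namespace`.
#' @export
read_gmt <- function(path, namespace = c("entrez", "ensembl")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(pathway_set(character(), character(), list(), namespace))
  }
  ids <- character(length(lines))
  nms <- character(length(lines))
  members <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    mem <- unique(f[-(1:2)])
    mem <- mem[nzchar(mem)]
    if (!length(mem)) stop("GMT line ", i, " has an empty member set")
    digit <- grepl("^[0-9]+$", mem)
    ens <- grepl("^ENS", mem)
    if (any(digit) && any(ens)) {
      stop("GMT line ", i, " mixes entrez-style and ensembl-style IDs")
    }
    nms[i] <- f[1]
    ids[i] <- f[2]
    members[[i]] <- mem
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ID in GMT: ", ids[duplicated(ids)][1])
  }
  names(members) <- ids
  pathway_set(ids, nms, members, namespace)
}

pathway_set <- function(id, name, members, namespace) {
  structure(list(id = id, name = name, members = members,
                 namespace = namespace),
            class = "PathwaySet")
}

#' @export
print.PathwaySet <- function(x, ...) {
  cat("PathwaySet: ", length(x$id), " pathways (", x$namespace,
      " namespace), sizes ", paste(lengths(x$members), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Write a pathway set to GMT
#'
#' Inverse of [read_gmt()]: emits `name<TAB>id<TAB>members...` per pathway,
#' members sorted for determinism.
#'
#' @param pathways a `PathwaySet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_along(pathways$id), function(i) {
    paste(c(pathways$name[i], pathways$id[i],
            sort(pathways$members[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a miRNA-target interaction database
#'
#' Loads a tab-separated table with columns `mirna`, `target` and, for the
#' functional database, `evidence`. TargetScan and miRDB are predictive
#' databases and carry no evidence strings; miRTarBase is functional and,
#' by default, has every pair whose evidence matches the weak pattern
#' (substring "weak", case-insensitive — e.g. "Functional MTI (Weak)")
#' removed at load time.
#'
#' @param path database file path.
#' @param name "targetscan", "mirdb" or "mirtarbase".
#' @param drop_weak drop weak-evidence pairs (functional database only).
#' @param weak_pattern regex identifying weak evidence (case-insensitive).
#' @return object of class `TargetDB`: list with `name`, `kind`
#'   ("predictive"/"functional"), `pairs` (data.frame `mirna`, `target`,
#'   `evidence`).
#' @export
read_target_db <- function(path, name = c("targetscan", "mirdb", "mirtarbase"),
                           drop_weak = TRUE, weak_pattern = "weak") {
  name <- match.arg(name)
  if (!file.exists(path)) stop("target database file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("mirna", "target") %in% names(tab))) {
    stop("target database must have 'mirna' and 'target' columns: ", path)
  }
  kind <- if (name == "mirtarbase") "functional" else "predictive"
  if (kind == "functional") {
    if (!"evidence" %in% names(tab)) {
      stop("mirtarbase table must have an 'evidence' column: ", path)
    }
    if (isTRUE(drop_weak)) {
      weak <- grepl(weak_pattern, tab$evidence, ignore.case = TRUE)
      tab <- tab[!weak, , drop = FALSE]
    }
  } else {
    tab$evidence <- rep(NA_character_, nrow(tab))
  }
  pairs <- unique(tab[, c("mirna", "target", "evidence")])
  pairs <- pairs[order(pairs$mirna, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(name = name, kind = kind, pairs = pairs),
            class = "TargetDB")
}

#' @export
print.TargetDB <- function(x, ...) {
  cat("TargetDB '", x$name, "' (", x$kind, "): ", nrow(x$pairs),
      " pairs\n", sep = "")
  invisible(x)
}

# fast membership test for (mirna, target) pairs
db_has_pair <- function(db, mirna, target) {
  paste(mirna, target, sep = "\r") %in%
    paste(db$pairs$mirna, db$pairs$target, sep = "\r")
}
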