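#' Domain records
#'
#' A `domain_records` object holds one row per protein (or synthetic) domain:
#' an identifier, its amino-acid sequence, an optional CATH label
#' (dotted `"C.A.T.H"` string with up to four integer fields), and an
#' optional per-residue 3-state secondary-structure string over `{H, E, L}`.
#' Positions are 1-based throughout the package and in all files it writes.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid strings.
#' @param cath_label Optional character vector of dotted CATH labels
#'   (`NA` allowed per record).
#' @param ss3 Optional character vector of 3-state strings; when present and
#'   non-`NA`, must have the same number of characters as the sequence.
#' @return A data frame of class `domain_records` with columns
#'   `id`, `sequence`, `cath_label`, `ss3`.
#' @export
domain_records <- function(id, sequence, cath_label = NULL, ss3 = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  n <- length(id)
  if (length(sequence) != n) stop("id and sequence lengths differ", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  cath_label <- if (is.null(cath_label)) rep(NA_character_, n) else as.character(cath_label)
  ss3 <- if (is.null(ss3)) rep(NA_character_, n) else toupper(as.character(ss3))
  if (length(cath_label) != n || length(ss3) != n) {
    stop("annotation vectors must match the number of records", call. = FALSE)
  }
  has_ss <- !is.na(ss3)
  if (any(has_ss)) {
    if (any(nchar(ss3[has_ss]) != nchar(sequence[has_ss]))) {
      bad <- id[has_ss][nchar(ss3[has_ss]) != nchar(sequence[has_ss])]
      stop("ss3 length differs from sequence length for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(unique(strsplit(paste(ss3[has_ss], collapse = ""), "")[[1]]),
                     c("H", "E", "L"))
    if (length(extra)) {
      stop("ss3 contains states outside {H,E,L}: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    data.frame(id = id, sequence = sequence, cath_label = cath_label,
               ss3 = ss3, stringsAsFactors = FALSE),
    class = c("domain_records", "data.frame")
  )
}

#' @export
print.domain_records <- function(x, ...) {
  cat("<domain_records> ", nrow(x), " records, length ",
      if (nrow(x)) paste0(min(nchar(x$sequence)), "-", max(nchar(x$sequence))) else "-",
      "; cath: ", sum(!is.na(x$cath_label)),
      ", ss3: ", sum(!is.na(x$ss3)), "\n", sep = "")
  invisible(x)
}

#' Reduce DSSP 8-state annotations to 3 states
#'
#' Applies the standard reduction `H, G, I -> H` (helix), `E, B -> E`
#' (strand), `T, S, - -> L` (loop) characterwise.
#'
#' @param eight_state Character vector of 8-state strings over
#'   `{H,G,I,E,B,T,S,-}`.
#' @return Character vector of equal-length 3-state strings over `{H,E,L}`.
#' @export
#' @examples
#' reduce_dssp("HGIEBTS-") # "HHHEELLL"
reduce_dssp <- function(eight_state) {
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "L", S = "L", "-" = "L")
  vapply(as.character(eight_state), function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nchar(s)) return("")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- map[chars]
    if (anyNA(out)) {
      i <- which(is.na(out))[1]
      stop("unknown DSSP state '", chars[i], "' at position ", i, call. = FALSE)
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' CATH hierarchy levels
#' @return Character vector of the four level names, coarse to fine.
#' @export
cath_levels <- function() {
  c("Class", "Architecture", "Topology", "HomologousSuperfamily")
}

#' Truncate a CATH label to a hierarchy level
#'
#' Keeps the first 1/2/3/4 dotted fields of a `"C.A.T.H"` label for
#' Class/Architecture/Topology/HomologousSuperfamily respectively. Labels
#' with fewer than four fields are accepted as long as the requested level
#' is available.
#'
#' @param label Character vector of dotted CATH labels.
#' @param level One of [cath_levels()].
#' @return Character vector of truncated labels.
#' @export
#' @examples
#' truncate_cath("3.40.50.720", "Architecture") # "3.40"
truncate_cath <- function(label, level) {
  level <- match.arg(level, cath_levels())
  k <- match(level, cath_levels())
  vapply(as.character(label), function(lab) {
    if (is.na(lab)) return(NA_character_)
    fields <- strsplit(lab, ".", fixed = TRUE)[[1]]
    if (length(fields) < k) {
      stop("CATH label '", lab, "' has ", length(fields),
           " field(s); level ", level, " needs ", k, call. = FALSE)
    }
    paste(fields[seq_len(k)], collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

#' Define a suppression target
#'
#' A suppression specification names the structural category whose
#' language-modeling ability the subnetwork is trained to destroy: either a
#' sequence-level CATH category (all sequences whose truncated label matches
#' `target_label`) or a residue-level secondary-structure state (all
#' positions annotated `H`, `E` or `L`).
#'
#' @param level `"sequence"` or `"residue"`.
#' @param target_label For sequence level, a truncated CATH label whose
#'   number of dotted fields must match `cath_level`; for residue level,
#'   one of `"H"`, `"E"`, `"L"`.
#' @param cath_level Required at sequence level; one of [cath_levels()].
#' @return An object of class `suppression_spec`.
#' @export
suppression_spec <- function(level = c("sequence", "residue"),
                             target_label,
                             cath_level = NULL) {
  level <- match.arg(level)
  target_label <- as.character(target_label)
  if (length(target_label) != 1L) stop("target_label must be a single string", call. = FALSE)
  if (level == "residue") {
    if (!target_label %in% c("H", "E", "L")) {
      stop("residue-level target_label must be one of H, E, L", call. = FALSE)
    }
    cath_level <- NULL
  } else {
    if (is.null(cath_level)) stop("sequence-level spec requires cath_level", call. = FALSE)
    cath_level <- match.arg(cath_level, cath_levels())
    n_fields <- length(strsplit(target_label, ".", fixed = TRUE)[[1]])
    want <- match(cath_level, cath_levels())
    if (n_fields != want) {
      stop("target_label '", target_label, "' has ", n_fields,
           " field(s) but level ", cath_level, " requires ", want, call. = FALSE)
    }
  }
  structure(list(level = level, target_label = target_label,
                 cath_level = cath_level),
            class = "suppression_spec")
}

#' @export
print.suppression_spec <- function(x, ...) {
  if (x$level == "sequence") {
    cat("<suppression_spec> sequence-level, ", x$cath_level,
        " = '", x$target_label, "'\n", sep = "")
  } else {
    cat("<suppression_spec> residue-level, state '", x$target_label, "'\n", sep = "")
  }
  invisible(x)
}

#' Partition records into suppression and maintenance sides
#'
#' For a sequence-level spec, splits record ids into the suppressed set
#' (truncated CATH label equals the target) and its complement. For a
#' residue-level spec, computes per record the suppressed position set J*
#' (1-based positions annotated with the target state) and its complement
#' J'. The two sides are always disjoint and jointly exhaustive.
#'
#' @param records A [domain_records()] object.
#' @param spec A [suppression_spec()].
#' @return An object of class `suppression_partition`: for sequence level,
#'   fields `suppressed` / `maintained` (character id vectors); for residue
#'   level, fields `positions` (named list of 1-based integer vectors, the
#'   J* of each record) and `complement` (the J' of each record).
#' @export
build_partition <- function(records, spec) {
  stopifnot(inherits(records, "domain_records"), inherits(spec, "suppression_spec"))
  if (!nrow(records)) stop("no records to partition", call. = FALSE)
  if (spec$level == "sequence") {
    missing <- records$id[is.na(records$cath_label)]
    if (length(missing)) {
      stop("records missing cath_label: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    trunc <- truncate_cath(records$cath_label, spec$cath_level)
    hit <- trunc == spec$target_label
    if (!any(hit)) {
      stop("no record matches suppression target '", spec$target_label,
           "' at level ", spec$cath_level, call. = FALSE)
    }
    out <- list(level = "sequence", spec = spec,
                suppressed = records$id[hit],
                maintained = records$id[!hit])
  } else {
    missing <- records$id[is.na(records$ss3)]
    if (length(missing)) {
      stop("records missing ss3: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    pos <- lapply(strsplit(records$ss3, "", fixed = TRUE),
                  function(st) which(st == spec$target_label))
    comp <- lapply(strsplit(records$ss3, "", fixed = TRUE),
                   function(st) which(st != spec$target_label))
    names(pos) <- names(comp) <- records$id
    if (!any(lengths(pos) > 0L)) {
      stop("no position carries suppression state '", spec$target_label, "'",
           call. = FALSE)
    }
    out <- list(level = "residue", spec = spec,
                positions = pos, complement = comp)
  }
  structure(out, class = "suppression_partition")
}

#' @export
print.suppression_partition <- function(x, ...) {
  if (x$level == "sequence") {
    cat("<suppression_partition> sequence-level: ", length(x$suppressed),
        " suppressed / ", length(x$maintained), " maintained\n", sep = "")
  } else {
    cat("<suppression_partition> residue-level: ",
        sum(lengths(x$positions)), " suppressed positions across ",
        length(x$positions), " records\n", sep = "")
  }
  invisible(x)
}

#' Filter records by sequence length
#'
#' Keeps records whose sequence length lies in `[min_len, max_len]`, both
#' bounds inclusive. Defaults follow the usual masked-LM context-window
#' filter of 64 to 1024 residues.
#'
#' @param records A [domain_records()] object.
#' @param min_len,max_len Inclusive length bounds.
#' @return The filtered `domain_records`.
#' @export
filter_by_length <- function(records, min_len = 64L, max_len = 1024L) {
  stopifnot(inherits(records, "domain_records"))
  if (min_len > max_len) stop("min_len exceeds max_len", call. = FALSE)
  len <- nchar(records$sequence)
  out <- records[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("domain_records", "data.frame")
  out
}

#' Split records into train / validation / test partitions
#'
#' Uniform random split with the conventional 70/20/10 fractions.
#' Partition sizes are deterministic: validation and test receive the floor
#' of their fractional allocation and the remainder goes to train, so a
#' corpus of 10 records always splits 7/2/1. With `stratify_by_class = TRUE`
#' the split is carried out independently within each CATH Class so that
#' class composition is balanced across partitions.
#'
#' @param records A [domain_records()] object.
#' @param fractions Numeric length-3 vector `(train, validation, test)`
#'   summing to 1.
#' @param seed Integer seed; the same seed always yields the same split.
#' @param stratify_by_class Split within CATH Class strata (requires
#'   `cath_label` on every record).
#' @return An object of class `split_assignment`: a data frame with columns
#'   `id` and `partition`, plus attributes `seed` and `fractions`.
#' @export
split_dataset <- function(records, fractions = c(0.7, 0.2, 0.1), seed = 1L,
                          stratify_by_class = FALSE) {
  stopifnot(inherits(records, "domain_records"))
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("fractions must be three positive numbers", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  alloc_one <- function(ids, shuffled) {
    n <- length(ids)
    n_val <- floor(fractions[2] * n)
    n_test <- floor(fractions[3] * n)
    n_train <- n - n_val - n_test  # remainder goes to train
    part <- rep(c("train", "validation", "test"), c(n_train, n_val, n_test))
    data.frame(id = shuffled, partition = part, stringsAsFactors = FALSE)
  }
  out <- with_seed(seed, {
    if (stratify_by_class) {
      if (anyNA(records$cath_label)) {
        stop("stratified split requires cath_label on every record", call. = FALSE)
      }
      strata <- split(records$id, truncate_cath(records$cath_label, "Class"))
      do.call(rbind, lapply(strata, function(ids) alloc_one(ids, sample(ids))))
    } else {
      alloc_one(records$id, sample(records$id))
    }
  })
  rownames(out) <- NULL
  structure(out, seed = as.integer(seed), fractions = fractions,
            class = c("split_assignment", "data.frame"))
}

#' @export
print.split_assignment <- function(x, ...) {
  tb <- table(factor(x$partition, levels = c("train", "validation", "test")))
  cat("<split_assignment> ", paste(names(tb), as.integer(tb), sep = "=", collapse = ", "),
      " (seed ", attr(x, "seed"), ")\n", sep = "")
  invisible(x)
}

#' Ids of one split partition
#' @param split A [split_dataset()] result.
#' @param partition `"train"`, `"validation"` or `"test"`.
#' @return Character vector of ids.
#' @export
split_ids <- function(split, partition = c("train", "validation", "test")) {
  partition <- match.arg(partition)
  split$id[split$partition == partition]
}
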