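# EC handling, family reaction-category classification, pathway enrichment
# and cofactor summaries.

#' Split EC number strings into their four fields
#'
#' @param ec character vector like \code{"1.5.1.3"} or \code{"2.4.1.-"}.
#' @return data.frame with columns \code{ec}, \code{d1}..\code{d4}
#'   (character; "-" marks an unresolved field) and \code{dashed}.
#' @export
parseEC <- function(ec) {
  parts <- strsplit(ec, ".", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed EC number(s): ", paste(ec[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  data.frame(ec = ec, d1 = m[, 1], d2 = m[, 2], d3 = m[, 3], d4 = m[, 4],
             dashed = apply(m, 1, function(r) any(r == "-")),
             stringsAsFactors = FALSE)
}

#' Drop dashed (partially unresolved) EC numbers
#'
#' EC numbers with unknown fields cannot be mapped to pathways and are
#' removed before pathway mapping. Order is preserved; the number removed is
#' attached as attribute \code{"removed"}.
#'
#' @param ecs character vector of EC numbers.
#' @return filtered character vector with attribute \code{removed}.
#' @export
filterDashed <- function(ecs) {
  if (length(ecs) == 0L) {
    out <- character()
    attr(out, "removed") <- 0L
    return(out)
  }
  dashed <- parseEC(ecs)$dashed
  out <- ecs[!dashed]
  attr(out, "removed") <- sum(dashed)
  out
}

#' Classify a family's reaction heterogeneity from its EC numbers
#'
#' Families (F-groups) fall into four categories by the EC numbers of their
#' members: \code{null} (no EC assignment), \code{homogeneous} (a single
#' distinct EC), \code{heterogeneous_substrate} (several ECs all sharing the
#' first three fields, i.e. same reaction chemistry on different substrates)
#' and \code{heterogeneous_reaction} (ECs differing in the first three
#' fields). Dashed ECs count as assignments here; dash-removal applies only
#' to pathway mapping.
#'
#' @param ecs character vector of the family's EC numbers (possibly empty).
#' @return one of \code{"null"}, \code{"homogeneous"},
#'   \code{"heterogeneous_substrate"}, \code{"heterogeneous_reaction"}.
#' @export
classifyFGroup <- function(ecs) {
  ecs <- unique(ecs[!is.na(ecs) & nzchar(ecs)])
  if (length(ecs) == 0L) return("null")
  if (length(ecs) == 1L) return("homogeneous")
  p <- parseEC(ecs)
  if (length(unique(paste(p$d1, p$d2, p$d3))) == 1L)
    return("heterogeneous_substrate")
  "heterogeneous_reaction"
}

#' Build family (F-group) records from structure annotations
#'
#' Structures carrying the same sorted F-group combination form one family
#' record (a multi-domain combination is a distinct key). EC numbers are
#' pooled per family; a family is multifunctional when any single structure
#' carries two or more ECs.
#'
#' @param structure_fgroups data.frame with columns \code{structure},
#'   \code{fgroup}.
#' @param structure_ecs data.frame with columns \code{structure}, \code{ec}.
#' @return data.frame with columns \code{key}, \code{n_structures},
#'   \code{n_ecs}, \code{category}, \code{multifunctional}, and a list
#'   column \code{ecs}.
#' @export
buildFGroupRecords <- function(structure_fgroups, structure_ecs) {
  key_by_struct <- tapply(structure_fgroups$fgroup, structure_fgroups$structure,
                          function(f) paste(sort(unique(f)), collapse = "+"))
  ecs_by_struct <- tapply(structure_ecs$ec, structure_ecs$structure,
                          function(e) unique(e))
  keys <- unname(key_by_struct)
  structs <- names(key_by_struct)
  out <- lapply(unique(keys), function(k) {
    members <- structs[keys == k]
    ec_list <- ecs_by_struct[members]
    ecs <- unique(unlist(ec_list, use.names = FALSE))
    ecs <- ecs[!is.na(ecs)]
    multi <- any(vapply(ec_list, function(e)
      length(e[!is.na(e)]) >= 2L, logical(1)), na.rm = TRUE)
    data.frame(key = k, n_structures = length(members),
               n_ecs = length(ecs), category = classifyFGroup(ecs),
               multifunctional = isTRUE(multi), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$ecs <- lapply(unique(keys), function(k) {
    members <- structs[keys == k]
    e <- unique(unlist(ecs_by_struct[members], use.names = FALSE))
    e[!is.na(e)]
  })
  res
}

#' Over/under-representation of a pathway class
#'
#' Observed frequency = motif-bearing (RLM) ECs of the class over all RLM ECs
#' in the major group; expected frequency = all ECs of the class over all ECs
#' in the group; the enrichment ratio is observed/expected. Significance is a
#' two-sided Fisher's exact test on the 2x2 table of class membership vs RLM
#' status (p-values are reported raw; the per-class significance marks in the
#' source analysis are uncorrected).
#'
#' @param class_rlm RLM ECs in the class.
#' @param class_all all ECs in the class.
#' @param group_rlm RLM ECs in the whole major group.
#' @param group_all all ECs in the whole major group.
#' @param alpha significance level for the flag.
#' @return data.frame row: observed, expected, ratio, p.value, significant.
#' @export
enrichmentTest <- function(class_rlm, class_all, group_rlm, group_all,
                           alpha = 0.05) {
  if (group_rlm <= 0 || group_all <= 0)
    stop("group counts must be positive")
  tab <- matrix(c(class_rlm, group_rlm - class_rlm,
                  class_all - class_rlm,
                  (group_all - group_rlm) - (class_all - class_rlm)),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent counts give negative table cells")
  observed <- class_rlm / group_rlm
  expected <- class_all / group_all
  p <- stats::fisher.test(tab)$p.value
  data.frame(observed = observed, expected = expected,
             ratio = if (expected > 0) observed / expected else NA_real_,
             p.value = p, significant = p < alpha)
}

#' Enrichment table over all classes of a major group
#'
#' @param class_counts data.frame with columns \code{class},
#'   \code{class_rlm}, \code{class_all}.
#' @param group_rlm,group_all totals for the major group.
#' @return data.frame with one row per class.
#' @export
enrichmentTable <- function(class_counts, group_rlm, group_all) {
  rows <- lapply(seq_len(nrow(class_counts)), function(i)
    cbind(class = class_counts$class[i],
          enrichmentTest(class_counts$class_rlm[i],
                         class_counts$class_all[i],
                         group_rlm, group_all),
          stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Rounded integer percentage
#'
#' \code{round(100 * part / whole)} with half-up rounding, the convention
#' used for printed count ratios like "68\% (21 out of 31)".
#'
#' @param part,whole non-negative counts, \code{part <= whole},
#'   \code{whole > 0}; vectorized.
#' @return integer percent.
#' @export
percentReport <- function(part, whole) {
  stopifnot(all(whole > 0), all(part >= 0), all(part <= whole))
  as.integer(floor(100 * part / whole + 0.5))
}

# canonical cofactor labels: hybrid iron-sulfur cluster variants collapse to
# two types regardless of composition
.normalize_cofactor <- function(x) {
  y <- x
  y[grepl("Fe-?O-?S", y, ignore.case = TRUE)] <- "[Fe-O-S]"
  y[grepl("(Ni-?Fe-?S|Fe-?Ni-?S)", y, ignore.case = TRUE)] <- "[Ni-Fe-S]"
  y
}

#' Summarise inorganic cofactors across enzymes and families
#'
#' Joins an EC-to-cofactor table with family records, collapsing hybrid
#' iron-sulfur cluster variants into the two canonical types ([Fe-O-S] and
#' [Ni-Fe-S]). Reports, per cofactor type, the number of distinct ECs and
#' families, and per cofactor group the EC top-class breakdown as rounded
#' percentages.
#'
#' @param ec_cofactor data.frame with columns \code{ec}, \code{cofactor}.
#' @param ec_fgroup optional data.frame with columns \code{ec},
#'   \code{fgroup}.
#' @return list with \code{summary} (per cofactor type) and
#'   \code{class_breakdown} (per cofactor type and EC top class: count and
#'   percent).
#' @export
cofactorJoin <- function(ec_cofactor, ec_fgroup = NULL) {
  if (nrow(ec_cofactor) == 0L)
    return(list(summary = data.frame(cofactor = character(),
                                     n_ecs = integer(), n_fgroups = integer()),
                class_breakdown = data.frame(cofactor = character(),
                                             ec_class = integer(),
                                             n = integer(),
                                             percent = integer())))
  tab <- ec_cofactor
  tab$cofactor <- .normalize_cofactor(tab$cofactor)
  tab <- unique(tab[, c("ec", "cofactor")])
  summ <- do.call(rbind, lapply(split(tab, tab$cofactor), function(g) {
    nfg <- if (!is.null(ec_fgroup))
      length(unique(ec_fgroup$fgroup[ec_fgroup$ec %in% g$ec]))
    else NA_integer_
    data.frame(cofactor = g$cofactor[1], n_ecs = length(unique(g$ec)),
               n_fgroups = nfg, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  bd <- do.call(rbind, lapply(split(tab, tab$cofactor), function(g) {
    ecs <- unique(g$ec)
    cls <- parseEC(ecs)$d1
    t <- table(cls)
    data.frame(cofactor = g$cofactor[1], ec_class = names(t),
               n = as.integer(t),
               percent = percentReport(as.integer(t), length(ecs)),
               stringsAsFactors = FALSE)
  }))
  rownames(bd) <- NULL
  list(summary = summ, class_breakdown = bd)
}
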