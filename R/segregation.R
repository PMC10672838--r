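#' Thresholds quantifying "present in a large majority"
#'
#' A gene counts as present in a phenotype group when the fraction of that
#' group's genomes carrying it is at least `presence_min`, and absent when
#' the fraction is at most `absence_max`.
#'
#' @param presence_min fraction in (0.5, 1\]; default 0.8.
#' @param absence_max fraction in \[0, 0.5); default 0.2.
#' @return object of class `segregation_thresholds`.
#' @export
segregation_thresholds <- function(presence_min = 0.8, absence_max = 0.2) {
  if (!(presence_min > 0.5 && presence_min <= 1))
    stopf("presence_min must lie in (0.5, 1]")
  if (!(absence_max >= 0 && absence_max < 0.5))
    stopf("absence_max must lie in [0, 0.5)")
  structure(list(presence_min = presence_min, absence_max = absence_max),
            class = "segregation_thresholds")
}

#' Per-class presence fractions of one gene family
#' @param pm a [presence_matrix()].
#' @param family_id family to look up.
#' @return c(f_multi, f_uni): fraction of multipartite (resp. unipartite)
#'   genomes carrying the family.
#' @export
presence_fractions <- function(pm, family_id) {
  if (!family_id %in% family_ids(pm))
    stopf("unknown family: %s", family_id)
  col <- pm$bits[, family_id]
  c(f_multi = mean(col[pm$phenotype == "multipartite"]),
    f_uni = mean(col[pm$phenotype == "unipartite"]))
}

#' Assign one gene to Set 1 / Set 2 / Set 3 by its presence pattern
#'
#' Set 1: present in (a large majority of) multipartite genomes and absent
#' from their unipartite relatives; Set 2: the mirror image; Set 3:
#' everything else. The assignment is total: every fraction pair maps to
#' exactly one set.
#'
#' @param fractions c(f_multi, f_uni) from [presence_fractions()].
#' @param thresholds a [segregation_thresholds()].
#' @return "Set1", "Set2" or "Set3".
#' @export
assign_set <- function(fractions, thresholds = segregation_thresholds()) {
  stopifnot(inherits(thresholds, "segregation_thresholds"))
  f_m <- fractions[[1]]; f_u <- fractions[[2]]
  if (f_m >= thresholds$presence_min && f_u <= thresholds$absence_max)
    return("Set1")
  if (f_u >= thresholds$presence_min && f_m <= thresholds$absence_max)
    return("Set2")
  "Set3"
}

#' Segregate a list of discriminatory genes into Sets 1-3
#'
#' @param pm a [presence_matrix()].
#' @param families character vector of family ids (e.g. the Intersection
#'   Set); defaults to all families of the matrix.
#' @param thresholds a [segregation_thresholds()].
#' @param annotation optional data.frame (family_id, category) joined onto
#'   the report, e.g. user-supplied COG categories.
#' @return data.frame (class `segregation_result`): family_id, display_name,
#'   f_multi, f_uni, assigned_set (+ category when supplied). The three
#'   sets partition `families`.
#' @export
segregate_sets <- function(pm, families = NULL,
                           thresholds = segregation_thresholds(),
                           annotation = NULL) {
  families <- families %||% family_ids(pm)
  miss <- setdiff(families, family_ids(pm))
  if (length(miss)) stopf("unknown family id(s): %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  is_multi <- pm$phenotype == "multipartite"
  f_m <- colMeans(pm$bits[is_multi, families, drop = FALSE])
  f_u <- colMeans(pm$bits[!is_multi, families, drop = FALSE])
  assigned <- ifelse(f_m >= thresholds$presence_min & f_u <= thresholds$absence_max,
                     "Set1",
              ifelse(f_u >= thresholds$presence_min & f_m <= thresholds$absence_max,
                     "Set2", "Set3"))
  disp <- attr(pm, "display_name")
  out <- data.frame(family_id = families,
                    display_name = if (is.null(disp)) families
                                   else unname(disp[families]),
                    f_multi = unname(f_m), f_uni = unname(f_u),
                    assigned_set = unname(assigned),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    stopifnot(all(c("family_id", "category") %in% names(annotation)))
    out$category <- annotation$category[match(out$family_id,
                                              annotation$family_id)]
  }
  structure(out, class = c("segregation_result", "data.frame"))
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("segregation_result: %d genes -> Set1 %d, Set2 %d, Set3 %d\n",
              nrow(x), sum(x$assigned_set == "Set1"),
              sum(x$assigned_set == "Set2"), sum(x$assigned_set == "Set3")))
  NextMethod()
}
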