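# Bundled case study: light cableway skidding vs. road-skidding in a
# subtropical forest area (Shaowu, Fujian). Shipped as plain-text files under
# inst/extdata and loaded here.

#' Forest harvesting case study: cableway vs. road skidding
#'
#' Loads the bundled evaluation of two timber-skidding alternatives -- light
#' cableway skidding and traditional road-skidding -- against a four-level
#' sustainability hierarchy: one target, 3 benefit criteria (ecological,
#' economic, social), 9 sub-criteria and 39 leaf indicators. The hierarchy
#' ships with its published local weights; the aggregated expert judgment
#' matrices are included for the target node (criteria comparison) and for
#' the natural-ecology sub-criterion (its five indicator leaves), so the
#' weight pipeline can be re-run end to end on those nodes. Leaf values are
#' the case's standardized "standard values" (fractions in \[0, 1\]); the
#' cost table records the field measurements per m^3 for both methods,
#' including the unit costs (148.44 vs. 104.65 yuan) behind the 29.50%
#' unit-cost savings rate of cableway skidding.
#'
#' @return A list with components:
#' \describe{
#'   \item{hierarchy}{`"fahp_hierarchy"` with 1 + 3 + 9 + 39 nodes and
#'     alternatives `"road"`, `"cableway"`, local weights filled.}
#'   \item{values}{Data frame `leaf`, `alternative`, `value` of standardized
#'     leaf values (78 rows).}
#'   \item{judgments}{Named list of aggregated complementary fuzzy judgment
#'     matrices: `A` (3 x 3 over B1..B3) and `C11` (5 x 5 over D1..D5).}
#'   \item{costs}{Data frame of the per-m^3 field cost/efficiency
#'     measurements for both skidding methods.}
#' }
#' @examples
#' case <- skidding_case()
#' fit <- fahp(case$hierarchy, case$values)
#' round(fit$scores, 4)
#' @export
skidding_case <- function() {
  path <- function(f) system.file("extdata", f, package = "fahp", mustWork = TRUE)
  hierarchy <- read_hierarchy(path("skidding_hierarchy.yaml"))
  values <- utils::read.csv(path("skidding_values.csv"), stringsAsFactors = FALSE)
  jd <- utils::read.csv(path("skidding_judgments.csv"), stringsAsFactors = FALSE)
  judgments <- lapply(split(jd, jd$node), function(d) {
    ch <- hierarchy_children(hierarchy, d$node[[1L]])
    f <- matrix(0.5, length(ch), length(ch), dimnames = list(ch, ch))
    for (k in seq_len(nrow(d))) {
      f[d$i[k], d$j[k]] <- d$score[k]
      f[d$j[k], d$i[k]] <- 1 - d$score[k]
    }
    check_judgment(f)
  })
  costs <- utils::read.csv(path("skidding_costs.csv"), stringsAsFactors = FALSE,
                           check.names = FALSE)
  list(hierarchy = hierarchy, values = values, judgments = judgments, costs = costs)
}
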