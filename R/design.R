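#' Study design of the 39-study ovarian cancer consortium analysis
#'
#' Per-study case and control counts, case-only status, availability of
#' height and confounder data, and the regional grouping used to pair
#' case-only studies with controls from case-control studies. These numbers
#' define the "consortium-shaped" simulation design: 16,395 cases (14,549
#' invasive, 1,691 borderline, 155 of unknown behaviour) and 23,003 controls
#' across 39 studies. Nine studies contributed cases only and are analysed
#' with the controls of a case-control study from the same region; the six
#' UK studies form a single group.
#'
#' @param scale positive divisor applied to all counts (counts are rounded
#'   to the nearest integer). `scale = 5` gives a down-scaled design with
#'   the same structure, suitable for repeated simulation.
#' @return a data.frame with one row per study: `study`, `n_invasive`,
#'   `n_borderline`, `n_unknown`, `n_controls`, `case_only`, `has_height`,
#'   `has_confounders`, `group`.
#' @examples
#' d <- ocac_design()
#' sum(d$n_invasive + d$n_borderline + d$n_unknown)  # 16395
#' @export
ocac_design <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale > 0)
  d <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
study n_invasive n_borderline n_all n_controls
AUS 859 1 860 977
BAV 96 5 102 143
BEL 275 0 275 1347
DOV 904 327 1231 1487
GER 189 24 213 413
GRR 125 0 125 0
HAW 60 20 80 157
HJO 261 13 290 273
HMO 142 0 143 138
HOC 210 8 239 447
HOP 567 71 723 1464
HSK 147 9 156 0
LAX 278 0 278 0
MAL 440 138 578 828
MAY 699 79 778 743
MCC 66 0 66 66
MDA 375 0 375 384
MSK 450 0 450 593
NCO 722 171 896 792
NEC 654 232 904 1009
NJO 169 0 169 181
NOR 236 12 248 371
NTH 292 3 295 323
ORE 55 9 65 0
OVA 640 161 801 748
POC 423 0 423 417
POL 236 0 236 223
PVD 168 0 168 0
RMH 148 7 155 0
SEA 1447 76 1530 6004
SOC 268 20 288 0
SRO 158 0 158 0
STA 251 10 261 313
TOR 603 0 605 440
UCI 277 141 418 367
UKO 718 0 718 1104
UKR 47 0 47 0
USC 693 152 845 1047
WOC 201 2 203 204
")
  d$n_unknown <- d$n_all - d$n_invasive - d$n_borderline
  d$n_all <- NULL
  d$case_only <- d$n_controls == 0L
  height_studies <- c("AUS", "BAV", "DOV", "GER", "HAW", "HOP", "HSK", "MAL",
                      "MAY", "MCC", "NCO", "NEC", "NJO", "NTH", "POL", "PVD",
                      "SEA", "STA", "TOR", "UCI", "UKO", "USC")
  confounder_studies <- c("AUS", "DOV", "GER", "HAW", "HOP", "MAL", "NCO",
                          "NEC", "NJO", "NTH", "POL", "STA", "TOR", "UCI",
                          "UKO", "USC")
  d$has_height <- d$study %in% height_studies
  d$has_confounders <- d$study %in% confounder_studies
  grouping <- ocac_grouping()
  d$group <- grouping$group[match(d$study, grouping$study)]
  if (scale != 1) {
    for (col in c("n_invasive", "n_borderline", "n_unknown", "n_controls")) {
      d[[col]] <- as.integer(round(d[[col]] / scale))
    }
  }
  d
}

#' Regional grouping map for case-only studies
#'
#' Case-only studies contribute no controls and are merged, before the
#' per-study second-stage fits, with a case-control study from the same
#' region: HSK with GER, GRR with HOP, PVD with MAL, ORE with DOV, LAX with
#' UCI, and RMH/SOC/SRO/UKR with SEA and UKO as a single UK group. All other
#' studies form their own group.
#'
#' @return data.frame with columns `study` and `group`.
#' @export
ocac_grouping <- function() {
  studies <- c("AUS", "BAV", "BEL", "DOV", "GER", "GRR", "HAW", "HJO", "HMO",
               "HOC", "HOP", "HSK", "LAX", "MAL", "MAY", "MCC", "MDA", "MSK",
               "NCO", "NEC", "NJO", "NOR", "NTH", "ORE", "OVA", "POC", "POL",
               "PVD", "RMH", "SEA", "SOC", "SRO", "STA", "TOR", "UCI", "UKO",
               "UKR", "USC", "WOC")
  group <- studies
  group[studies %in% c("HSK", "GER")] <- "GER"
  group[studies %in% c("GRR", "HOP")] <- "HOP"
  group[studies %in% c("PVD", "MAL")] <- "MAL"
  group[studies %in% c("ORE", "DOV")] <- "DOV"
  group[studies %in% c("LAX", "UCI")] <- "UCI"
  group[studies %in% c("RMH", "SOC", "SRO", "UKR", "SEA", "UKO")] <- "UK"
  data.frame(study = studies, group = group, stringsAsFactors = FALSE)
}
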