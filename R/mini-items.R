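#' The 48 binary MINI comorbidity items
#'
#' Catalogue of the 48 yes/no psychiatric comorbidity indicators from the
#' Mini International Neuropsychiatric Interview (MINI-PLUS) used as model
#' inputs, after removal of the schizophrenia-spectrum modules. The full
#' published item list is not publicly available, so this catalogue is a
#' synthetic reconstruction: the five items whose indices and labels are
#' fixed by the analyses this package reproduces (items 1, 2, 8, 11 and 40)
#' carry their documented labels, and the remainder are plausible MINI-PLUS
#' module labels arranged into diagnostic blocks (mood, suicidality,
#' anxiety, substance, other) that drive the co-occurrence structure of the
#' synthetic cohort generator.
#'
#' @return A data.frame with 48 rows and columns `item` (integer index),
#'   `name` (column name, `mini_c01` ... `mini_c48`), `label` (human-readable
#'   item label) and `block` (diagnostic block used by the correlated-binary
#'   co-occurrence model).
#' @examples
#' head(mini_items())
#' @export
mini_items <- function() {
  labels <- c(
    "major depressive episode: current",                      # 1 (pinned)
    "major depressive episode: recurrent",                    # 2 (pinned)
    "major depressive episode: past",
    "dysthymia: current",
    "dysthymia: past",
    "hypomanic episode: current",
    "hypomanic episode: past",
    "major depressive episode with melancholic features: recurrent", # 8 (pinned)
    "manic episode: current",
    "manic episode: past",
    "suicidality: current",                                   # 11 (pinned)
    "suicidality: past",
    "panic disorder: current",
    "panic disorder: lifetime",
    "agoraphobia: current",
    "social phobia: current",
    "specific phobia: current",
    "obsessive-compulsive disorder: current",
    "post-traumatic stress disorder: current",
    "generalized anxiety disorder: current",
    "panic disorder with agoraphobia: current",
    "agoraphobia without panic: lifetime",
    "social phobia: generalized",
    "obsessive-compulsive disorder: past",
    "post-traumatic stress disorder: past",
    "generalized anxiety disorder: past",
    "anorexia nervosa: current",
    "anorexia nervosa: binge/purge type",
    "bulimia nervosa: current",
    "bulimia nervosa: past",
    "somatization disorder: current",
    "hypochondriasis: current",
    "body dysmorphic disorder: current",
    "pain disorder: current",
    "attention-deficit/hyperactivity disorder: current",
    "conduct disorder: past",
    "oppositional defiant disorder: past",
    "adjustment disorder: current",
    "alcohol dependence: past 12 months",
    "substance abuse: past 12 months",                        # 40 (pinned)
    "alcohol abuse: past 12 months",
    "substance dependence: past 12 months",
    "alcohol dependence: lifetime",
    "substance dependence: lifetime",
    "antisocial personality disorder: lifetime",
    "premenstrual dysphoric disorder: current",
    "mixed anxiety-depressive disorder: current",
    "seasonal affective pattern: current"
  )
  block <- c(
    rep("mood", 10),
    rep("suicidality", 2),
    rep("anxiety", 14),
    rep("other", 12),
    rep("substance", 6),
    rep("other", 4)
  )
  data.frame(
    item = seq_len(48L),
    name = sprintf("mini_c%02d", seq_len(48L)),
    label = labels,
    block = block,
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
mini_item_names <- function() mini_items()$name

# PANSS items entering the symptomatic-remission severity rule
# (P1 delusions, P2 conceptual disorganisation, P3 hallucinations,
#  N1 blunted affect, N4 social withdrawal, N6 lack of spontaneity,
#  G5 mannerisms/posturing, G9 unusual thought content).
#' @keywords internal
andreasen_items <- function() {
  c("panss_p1", "panss_p2", "panss_p3",
    "panss_n1", "panss_n4", "panss_n6",
    "panss_g5", "panss_g9")
}
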