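# Worked-example fixtures: small terminology sets that reproduce the published
# inconsistency examples of the JFMDA 1st-edition audit (dual-role hierarchy
# rows, preferred/synonym swaps, polyhierarchy rows, multi-definition and
# multi-mapping terms, and the eight labels shared by both problem domains).
# Category placeholders (e.g. "c3-01") stand in for category cells the
# published examples do not print.

#' Worked-example terminology fixtures
#'
#' Returns ready-made [terminology_set()] fixtures encoding the published
#' worked examples, keyed by the kind of inconsistency they carry:
#'
#' * `table2` — two-layer hierarchy rows where the middle label is a category
#'   term in one terminology and a preferred term in another (device and
#'   patient); includes the identical-label rows (誤穿刺, 不明) and the
#'   patient-domain 損傷/外傷 inversion (a 2-cycle).
#' * `table3` — preferred/synonym swap rows.
#' * `table4` — polyhierarchy rows; `table4_deformation` isolates 変形 with
#'   its 11 category parents.
#' * `table5` — multi-definition rows; `table5_infection` isolates 感染 with
#'   its 8 exact-string-distinct definitions.
#' * `table6` — multi-mapping rows; `table6_perforation` isolates 穿孔 with
#'   its 4 CDRH-NCIt targets.
#' * `table7` — the 8 terms used in both problem domains, plus one
#'   domain-unique distractor per domain.
#'
#' @return named list; each element is a list of `terminology_set`s.
#' @export
table_fixtures <- function() {
  rec <- term_record
  list(
    table2 = table2_sets(),
    table3 = table3_sets(),
    table4 = table4_sets(),
    table4_deformation = list(terminology_set("T4D", lapply(
      TABLE4_DEVICE[["変形"]],
      function(p) rec("T4D", "device", p, "変形")))),
    table5 = table5_sets(),
    table5_infection = infection_sets(),
    table6 = table6_sets(),
    table6_perforation = list(terminology_set("T6P", list(
      rec("T6P", "patient", "c6-p4", "穿孔",
          cdrh_ncit_labels = c("Vessels, perforation of", "cardiac perforation",
                               "perforation", "injury"))))),
    table7 = table7_sets()
  )
}

# rows: category term / dual-role term / preferred term. Each row is realized
# as two records in two terminologies: (cat, mid) and (mid, pref).
TABLE2_DEVICE <- list(
  c("電気的不良", "ヒューズ切れ", "ヒューズ溶断"),
  c("機器不良", "アラーム異常", "異常検知不可"),
  c("不明", "不明", "原因不明"),
  c("故障", "バッテリ不良", "早期放電"),
  c("動作不良", "バッテリ不良", "バッテリ駆動不良"),
  c("誤穿刺", "誤穿刺", "誤穿刺")
)
TABLE2_PATIENT <- list(
  c("アレルギー症状", "かゆみ", "そう痒感"),
  c("機能性障害", "呼吸不全", "動脈血酸素飽和度低下"),
  c("炎症", "痛み", "のどの痛み"),
  c("炎症症状", "皮膚炎", "痒み"),
  c("損傷", "外傷", "損傷")
)

table2_sets <- function() {
  a <- list(); b <- list()
  for (row in TABLE2_DEVICE) {
    a[[length(a) + 1L]] <- term_record("T2-A", "device", row[1], row[2])
    b[[length(b) + 1L]] <- term_record("T2-B", "device", row[2], row[3])
  }
  for (row in TABLE2_PATIENT) {
    a[[length(a) + 1L]] <- term_record("T2-A", "patient", row[1], row[2])
    b[[length(b) + 1L]] <- term_record("T2-B", "patient", row[2], row[3])
  }
  list(terminology_set("T2-A", a), terminology_set("T2-B", b))
}

# rows: preferred term / swapped term / synonym. Realized as a record with the
# swapped term as synonym in one terminology and as preferred in another.
TABLE3_DEVICE <- list(
  c("剥離", "はがれ", "剥離"),
  c("変形", "へこみ", "陥没"),
  c("変形", "折れ", "折損"),
  c("変形", "曲がり", "湾曲"),
  c("誤作動", "誤動作", "意図しない動作"),
  c("挿入不能", "迷入", "網膜下迷入")
)
TABLE3_PATIENT <- list(
  c("意図しない組織損傷", "裂傷", "切り傷"),
  c("残留", "遺残", "異物残存"),
  c("感染症", "感染", "患者感染"),
  c("感染症", "感染", "合併症"),
  c("感染症", "感染", "職業感染"),
  c("感染", "感染症", "感染")
)

table3_sets <- function() {
  a <- list(); b <- list()
  i <- 0L
  for (dom in c("device", "patient")) {
    rows <- if (dom == "device") TABLE3_DEVICE else TABLE3_PATIENT
    for (row in rows) {
      i <- i + 1L
      a[[length(a) + 1L]] <- term_record("T3-A", dom, sprintf("c3-%02da", i),
                                         row[1], synonym_labels = row[2])
      b[[length(b) + 1L]] <- term_record("T3-B", dom, sprintf("c3-%02db", i),
                                         row[2], synonym_labels = row[3])
    }
  }
  list(terminology_set("T3-A", a), terminology_set("T3-B", b))
}

TABLE4_DEVICE <- list(
  "アーチファクト" = c("アーチファクト", "異常画像"),
  "バッテリ不良" = c("充電不良", "動作不良", "故障"),
  "劣化" = c("経時変化", "故障", "破損", "不良"),
  "変形" = c("故障", "破損", "成形不良", "変形不良", "コンタクトレンズ不良",
             "分注ノズル折損・変形", "機械的不良", "不良", "損傷",
             "意図しない効果", "品質不良")
)
TABLE4_PATIENT <- list(
  "かぶれ" = c("炎症症状", "炎症", "皮膚炎", "かぶれ"),
  "骨折" = c("骨折", "外傷", "損傷", "組織損傷", "組織障害"),
  "神経障害" = c("組織損傷", "機能性障害"),
  "失明" = c("視機能障害", "視力障害", "失明"),
  "アレルギー反応" = c("感染", "炎症", "ショック", "アレルギー症状",
                       "眼疾患", "損傷", "アレルギー反応")
)

table4_sets <- function() {
  recs <- list()
  for (dom in c("device", "patient")) {
    rows <- if (dom == "device") TABLE4_DEVICE else TABLE4_PATIENT
    for (pref in names(rows)) {
      for (parent in rows[[pref]]) {
        recs[[length(recs) + 1L]] <- term_record("T4", dom, parent, pref)
      }
    }
  }
  list(terminology_set("T4", recs))
}

INFECTION_DEFS <- c(
  "病原微生物が人体に侵入し、臓器や組織中で増殖し、種々の症状をもたらすこと",
  "病原微生物が人体に侵入し、臓器や組織中で増殖し、種々の症状をもたらすこと。",
  "微生物が、体内に侵入・定着した状態。",
  "微生物が人体に侵入、増殖、何らの症状が出現する症例",
  "病原微生物または感染性物質が人体に侵入し、臓器や組織中で増殖し、種々の症状をもたらすこと",
  paste0("微生物感染などによるもので、キズ口の周りが赤くなっていたり、",
         "ズキズキした痛みが続いたり、膿を持っていたり、熱や腫れ等の異常が認められる場合"),
  "微生物が人体に侵入、増殖、何らの症状が出現する症例。",
  "微生物が、体内に侵入・定着した状態をいう。"
)

FUSE_DEFS <- c("ヒューズが切断すること。", "過電流等によりヒューズが切れること")

SLACK_DEFS <- c(
  "ネジ、ロック等が緩むこと。",
  "ねじなどの締め付けが甘くなること。",
  "ネジ等が緩み、当該部位の物理的な保持・作用に支障をきたす状態の事",
  paste0("構成部品の固着部 (ねじ、接着等) の結合力が弱まり、",
         "正常状態に比べて部品が動いてしまうこと"),
  "接続不良となる接続部のがたつき。",
  "接続部分、固定などが緩むこと。",
  "装置又は器具の部分の固定が不良となること。",
  "通電不良となる接続部の固定力不足"
)

infection_sets <- function() {
  lapply(seq_along(INFECTION_DEFS), function(i) {
    id <- sprintf("T5-K%02d", i)
    terminology_set(id, list(term_record(id, "patient", "c5-k", "感染",
                                         definition_text = INFECTION_DEFS[i])))
  })
}

table5_sets <- function() {
  sets <- infection_sets()
  for (i in seq_along(FUSE_DEFS)) {
    id <- sprintf("T5-F%02d", i)
    sets[[length(sets) + 1L]] <- terminology_set(id, list(
      term_record(id, "device", "c5-f", "ヒューズ切れ",
                  definition_text = FUSE_DEFS[i])))
  }
  for (i in seq_along(SLACK_DEFS)) {
    id <- sprintf("T5-S%02d", i)
    sets[[length(sets) + 1L]] <- terminology_set(id, list(
      term_record(id, "device", "c5-s", "緩み",
                  definition_text = SLACK_DEFS[i])))
  }
  sets
}

TABLE6_DEVICE <- list(
  "ねじれ" = c("Material twisted", "kinked"),
  "アラーム誤作動" = c("Defective alarm", "improper alarm",
                       "device alarm system issue"),
  "アラーム音不良" = c("Device alarm system issue", "not audible alarm"),
  "変形" = c("Lens aberration, distortion of", "material distortion",
             "Quality, unsatisfactory or poor", "Material deformation",
             "component(s), broken", "material deformation", "bend",
             "material integrity issue")
)
TABLE6_PATIENT <- list(
  "巨大乳頭結膜炎" = c("Foreign body reaction", "hypersensitivity",
                       "conjunctivitis"),
  "湿疹" = c("Rash", "skin inflammation"),
  "アレルギー反応" = c("Hypersensitivity", "allergic reaction"),
  "穿孔" = c("Vessels, perforation of", "cardiac perforation", "perforation",
             "injury")
)

table6_sets <- function() {
  recs <- list()
  i <- 0L
  for (dom in c("device", "patient")) {
    rows <- if (dom == "device") TABLE6_DEVICE else TABLE6_PATIENT
    for (pref in names(rows)) {
      i <- i + 1L
      recs[[length(recs) + 1L]] <- term_record("T6", dom, sprintf("c6-%02d", i),
                                               pref, cdrh_ncit_labels = rows[[pref]])
    }
  }
  list(terminology_set("T6", recs))
}

TABLE7_TERMS <- c("損傷", "汚染", "発熱", "感染", "感電",
                  "その他の事象", "その他", "不明")

table7_sets <- function() {
  recs <- list()
  for (i in seq_along(TABLE7_TERMS)) {
    recs[[length(recs) + 1L]] <- term_record("T7", "device",
                                             sprintf("c7-d%02d", i),
                                             TABLE7_TERMS[i])
    recs[[length(recs) + 1L]] <- term_record("T7", "patient",
                                             sprintf("c7-p%02d", i),
                                             TABLE7_TERMS[i])
  }
  # domain-unique distractors that must not be flagged
  recs[[length(recs) + 1L]] <- term_record("T7", "device", "c7-d99", "装置固有事象")
  recs[[length(recs) + 1L]] <- term_record("T7", "patient", "c7-p99", "患者固有事象")
  list(terminology_set("T7", recs))
}
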