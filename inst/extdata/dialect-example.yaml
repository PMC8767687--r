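# Example table dialect. Absent keys fall back to the package defaults.
field_sep: ","
cell_sep: ","
width_fold: false
case_fold: false
header_map:
  terminology_id: ["terminology_id", "用語集ID"]
  problem_domain: ["problem_domain", "区分"]
  category_term: ["category_term", "カテゴリー用語"]
  preferred_term: ["preferred_term", "基本用語"]
  synonyms: ["synonyms", "同義語"]
  definition: ["definition", "定義"]
  cdrh_ncit: ["cdrh_ncit", "CDRH-NCIt"]
domain_map:
  device: ["device", "不具合"]
  patient: ["patient", "健康被害"]
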