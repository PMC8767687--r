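"terminology_id","problem_domain","category_term","preferred_term","synonyms","definition","cdrh_ncit","device_group_name"
"T2-A","device","電気的不良","ヒューズ切れ","","","",""
"T2-A","device","機器不良","アラーム異常","","","",""
"T2-A","device","不明","不明","","","",""
"T2-A","device","故障","バッテリ不良","","","",""
"T2-A","device","動作不良","バッテリ不良","","","",""
"T2-A","device","誤穿刺","誤穿刺","","","",""
"T2-A","patient","アレルギー症状","かゆみ","","","",""
"T2-A","patient","機能性障害","呼吸不全","","","",""
"T2-A","patient","炎症","痛み","","","",""
"T2-A","patient","炎症症状","皮膚炎","","","",""
"T2-A","patient","損傷","外傷","","","",""
"T2-B","device","ヒューズ切れ","ヒューズ溶断","","","",""
"T2-B","device","アラーム異常","異常検知不可","","","",""
"T2-B","device","不明","原因不明","","","",""
"T2-B","device","バッテリ不良","早期放電","","","",""
"T2-B","device","バッテリ不良","バッテリ駆動不良","","","",""
"T2-B","device","誤穿刺","誤穿刺","","","",""
"T2-B","patient","かゆみ","そう痒感","","","",""
"T2-B","patient","呼吸不全","動脈血酸素飽和度低下","","","",""
"T2-B","patient","痛み","のどの痛み","","","",""
"T2-B","patient","皮膚炎","痒み","","","",""
"T2-B","patient","外傷","損傷","","","",""
"T3-A","device","c3-01a","剥離","はがれ","","",""
"T3-A","device","c3-02a","変形","へこみ","","",""
"T3-A","device","c3-03a","変形","折れ","","",""
"T3-A","device","c3-04a","変形","曲がり","","",""
"T3-A","device","c3-05a","誤作動","誤動作","","",""
"T3-A","device","c3-06a","挿入不能","迷入","","",""
"T3-A","patient","c3-07a","意図しない組織損傷","裂傷","","",""
"T3-A","patient","c3-08a","残留","遺残","","",""
"T3-A","patient","c3-09a","感染症","感染","","",""
"T3-A","patient","c3-10a","感染症","感染","","",""
"T3-A","patient","c3-11a","感染症","感染","","",""
"T3-A","patient","c3-12a","感染","感染症","","",""
"T3-B","device","c3-01b","はがれ","剥離","","",""
"T3-B","device","c3-02b","へこみ","陥没","","",""
"T3-B","device","c3-03b","折れ","折損","","",""
"T3-B","device","c3-04b","曲がり","湾曲","","",""
"T3-B","device","c3-05b","誤動作","意図しない動作","","",""
"T3-B","device","c3-06b","迷入","網膜下迷入","","",""
"T3-B","patient","c3-07b","裂傷","切り傷","","",""
"T3-B","patient","c3-08b","遺残","異物残存","","",""
"T3-B","patient","c3-09b","感染","患者感染","","",""
"T3-B","patient","c3-10b","感染","合併症","","",""
"T3-B","patient","c3-11b","感染","職業感染","","",""
"T3-B","patient","c3-12b","感染症","感染","","",""
"T4","device","アーチファクト","アーチファクト","","","",""
"T4","device","異常画像","アーチファクト","","","",""
"T4","device","充電不良","バッテリ不良","","","",""
"T4","device","動作不良","バッテリ不良","","","",""
"T4","device","故障","バッテリ不良","","","",""
"T4","device","経時変化","劣化","","","",""
"T4","device","故障","劣化","","","",""
"T4","device","破損","劣化","","","",""
"T4","device","不良","劣化","","","",""
"T4","device","故障","変形","","","",""
"T4","device","破損","変形","","","",""
"T4","device","成形不良","変形","","","",""
"T4","device","変形不良","変形","","","",""
"T4","device","コンタクトレンズ不良","変形","","","",""
"T4","device","分注ノズル折損・変形","変形","","","",""
"T4","device","機械的不良","変形","","","",""
"T4","device","不良","変形","","","",""
"T4","device","損傷","変形","","","",""
"T4","device","意図しない効果","変形","","","",""
"T4","device","品質不良","変形","","","",""
"T4","patient","炎症症状","かぶれ","","","",""
"T4","patient","炎症","かぶれ","","","",""
"T4","patient","皮膚炎","かぶれ","","","",""
"T4","patient","かぶれ","かぶれ","","","",""
"T4","patient","骨折","骨折","","","",""
"T4","patient","外傷","骨折","","","",""
"T4","patient","損傷","骨折","","","",""
"T4","patient","組織損傷","骨折","","","",""
"T4","patient","組織障害","骨折","","","",""
"T4","patient","組織損傷","神経障害","","","",""
"T4","patient","機能性障害","神経障害","","","",""
"T4","patient","視機能障害","失明","","","",""
"T4","patient","視力障害","失明","","","",""
"T4","patient","失明","失明","","","",""
"T4","patient","感染","アレルギー反応","","","",""
"T4","patient","炎症","アレルギー反応","","","",""
"T4","patient","ショック","アレルギー反応","","","",""
"T4","patient","アレルギー症状","アレルギー反応","","","",""
"T4","patient","眼疾患","アレルギー反応","","","",""
"T4","patient","損傷","アレルギー反応","","","",""
"T4","patient","アレルギー反応","アレルギー反応","","","",""
"T5-K01","patient","c5-k","感染","","病原微生物が人体に侵入し、臓器や組織中で増殖し、種々の症状をもたらすこと","",""
"T5-K02","patient","c5-k","感染","","病原微生物が人体に侵入し、臓器や組織中で増殖し、種々の症状をもたらすこと。","",""
"T5-K03","patient","c5-k","感染","","微生物が、体内に侵入・定着した状態。","",""
"T5-K04","patient","c5-k","感染","","微生物が人体に侵入、増殖、何らの症状が出現する症例","",""
"T5-K05","patient","c5-k","感染","","病原微生物または感染性物質が人体に侵入し、臓器や組織中で増殖し、種々の症状をもたらすこと","",""
"T5-K06","patient","c5-k","感染","","微生物感染などによるもので、キズ口の周りが赤くなっていたり、ズキズキした痛みが続いたり、膿を持っていたり、熱や腫れ等の異常が認められる場合","",""
"T5-K07","patient","c5-k","感染","","微生物が人体に侵入、増殖、何らの症状が出現する症例。","",""
"T5-K08","patient","c5-k","感染","","微生物が、体内に侵入・定着した状態をいう。","",""
"T5-F01","device","c5-f","ヒューズ切れ","","ヒューズが切断すること。","",""
"T5-F02","device","c5-f","ヒューズ切れ","","過電流等によりヒューズが切れること","",""
"T5-S01","device","c5-s","緩み","","ネジ、ロック等が緩むこと。","",""
"T5-S02","device","c5-s","緩み","","ねじなどの締め付けが甘くなること。","",""
"T5-S03","device","c5-s","緩み","","ネジ等が緩み、当該部位の物理的な保持・作用に支障をきたす状態の事","",""
"T5-S04","device","c5-s","緩み","","構成部品の固着部 (ねじ、接着等) の結合力が弱まり、正常状態に比べて部品が動いてしまうこと","",""
"T5-S05","device","c5-s","緩み","","接続不良となる接続部のがたつき。","",""
"T5-S06","device","c5-s","緩み","","接続部分、固定などが緩むこと。","",""
"T5-S07","device","c5-s","緩み","","装置又は器具の部分の固定が不良となること。","",""
"T5-S08","device","c5-s","緩み","","通電不良となる接続部の固定力不足","",""
"T6","device","c6-01","ねじれ","","","Material twisted, kinked",""
"T6","device","c6-02","アラーム誤作動","","","Defective alarm, improper alarm, device alarm system issue",""
"T6","device","c6-03","アラーム音不良","","","Device alarm system issue, not audible alarm",""
"T6","device","c6-04","変形","","","""Lens aberration, distortion of"", material distortion, ""Quality, unsatisfactory or poor"", Material deformation, ""component(s), broken"", material deformation, bend, material integrity issue",""
"T6","patient","c6-05","巨大乳頭結膜炎","","","Foreign body reaction, hypersensitivity, conjunctivitis",""
"T6","patient","c6-06","湿疹","","","Rash, skin inflammation",""
"T6","patient","c6-07","アレルギー反応","","","Hypersensitivity, allergic reaction",""
"T6","patient","c6-08","穿孔","","","""Vessels, perforation of"", cardiac perforation, perforation, injury",""
"T7","device","c7-d01","損傷","","","",""
"T7","patient","c7-p01","損傷","","","",""
"T7","device","c7-d02","汚染","","","",""
"T7","patient","c7-p02","汚染","","","",""
"T7","device","c7-d03","発熱","","","",""
"T7","patient","c7-p03","発熱","","","",""
"T7","device","c7-d04","感染","","","",""
"T7","patient","c7-p04","感染","","","",""
"T7","device","c7-d05","感電","","","",""
"T7","patient","c7-p05","感電","","","",""
"T7","device","c7-d06","その他の事象","","","",""
"T7","patient","c7-p06","その他の事象","","","",""
"T7","device","c7-d07","その他","","","",""
"T7","patient","c7-p07","その他","","","",""
"T7","device","c7-d08","不明","","","",""
"T7","patient","c7-p08","不明","","","",""
"T7","device","c7-d99","装置固有事象","","","",""
"T7","patient","c7-p99","患者固有事象","","","",""
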