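# synthetic fixture: designed values, not measured data; layout mirrors a Permo-Triassic collecting programme
locality_id,palaeolat_deg,palaeolat_sigma_deg,time_bin,region
DASH,12,4,permian,"Gansu, China (synthetic)"
TROP,-60,3,permian,"Karoo, South Africa (synthetic)"
DAPT,-59,3,permian,"Karoo, South Africa (synthetic)"
TAPI,-62,3,permian,"Karoo, South Africa (synthetic)"
CYNB,-57,3,early_mid_triassic,"Karoo, South Africa (synthetic)"
LYST,-55,3,early_mid_triassic,"Karoo, South Africa (synthetic)"
JIUC,35,5,early_mid_triassic,"Xinjiang, China (synthetic)"
ERMA,33,5,early_mid_triassic,"Shanxi, China (synthetic)"
CYNC,-55,3,mid_late_triassic,"Karoo, South Africa (synthetic)"
ARGA,-30,4,mid_late_triassic,"Argana, Morocco (synthetic)"
ELLI,-43,3,mid_late_triassic,"Elliot, Lesotho (synthetic)"

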