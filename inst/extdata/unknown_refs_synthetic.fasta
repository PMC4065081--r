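>hypothetical_1_synthetic
MTTIIGEAIPPIHDFRAKAIAGSGQSVKTANVTEREFTQSPMNALFRNFLAEIEPGATAK
LNEDSANKYRPGIIRDRLRRRVQGMIPNTDRNLARQFDTVQILSDWKGHGTESMGAYDWY
>hypothetical_2_synthetic
MMAGAKKLQKAIIHFLAAFDARGLKVRITIIVGPVIRATMFHVAKEFELVPEVNMVIVFS
RGQKESVTIARFARRSDRDAFSLGNANVRAGMVPAPKLSTGTWEPKRIRLQFFLIRQGQG
EINLWAMGVLFAKYMKNSVDFHESRLAADV
>hypothetical_3_synthetic
MIEPKLFGISSDVTHRDRASKDVYKYIRIFILAEPARGTLVEQPLIPFDKTIYRLPPQDL
GDLDRFEFEERPQPENHDKQGQQAFKLDSGQKCITARTTP
>hypothetical_4_synthetic
MTSKLRGAPSQIIKDWDEEAGEVLGGQNLGGDLDEKHAYMAGAPDSKASDPQKSKDYTII
LENNRTPTFRNQLTKRVSHREIAGLKNIILEARKKLLVQRAIQVSAAQDLSAYGTDQQPS
SPVGVFSIYRARLGG
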