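gene
TP53
CDKN2A
NTRK3
B2M
PTCH1
BRAF
ROS1
PDGFRA
EGFR
KRAS
ALK
MET
ERBB2
STK11
KEAP1
RB1
PIK3CA
PTEN
NF1
SMARCA4
ARID1A
ATM
BRCA1
BRCA2
FGFR1
FGFR2
FGFR3
CCND1
CDK4
CDK6
MDM2
MYC
NRAS
HRAS
RET
DDR2
MAP2K1
AKT1
NOTCH1
FBXW7
PANX001
PANX002
PANX003
PANX004
PANX005
PANX006
PANX007
PANX008
PANX009
PANX010
PANX011
PANX012
PANX013
PANX014
PANX015
PANX016
PANX017
PANX018
PANX019
PANX020
PANX021
PANX022
PANX023
PANX024
PANX025
PANX026
PANX027
PANX028
PANX029
PANX030
PANX031
PANX032
PANX033
PANX034
PANX035
PANX036
PANX037
PANX038
PANX039
PANX040
PANX041
PANX042
PANX043
PANX044
PANX045
PANX046
PANX047
PANX048
PANX049
PANX050
PANX051
PANX052
PANX053
PANX054
PANX055
PANX056
PANX057
PANX058
PANX059
PANX060
PANX061
PANX062
PANX063
PANX064
PANX065
PANX066
PANX067
PANX068
PANX069
PANX070
PANX071
PANX072
PANX073
PANX074
PANX075
PANX076
PANX077
PANX078
PANX079
PANX080
PANX081
PANX082
PANX083
PANX084
PANX085
PANX086
PANX087
PANX088
PANX089
PANX090
PANX091
PANX092
PANX093
PANX094
PANX095
PANX096
PANX097
PANX098
PANX099
PANX100
PANX101
PANX102
PANX103
PANX104
PANX105
PANX106
PANX107
PANX108
PANX109
PANX110
PANX111
PANX112
PANX113
PANX114
PANX115
PANX116
PANX117
PANX118
PANX119
PANX120
PANX121
PANX122
PANX123
PANX124
PANX125
PANX126
PANX127
PANX128
PANX129
PANX130
PANX131
PANX132
PANX133
PANX134
PANX135
PANX136
PANX137
PANX138
PANX139
PANX140
PANX141
PANX142
PANX143
PANX144
PANX145
PANX146
PANX147
PANX148
PANX149
PANX150
PANX151
PANX152
PANX153
PANX154
PANX155
PANX156
PANX157
PANX158
PANX159
PANX160
PANX161
PANX162
PANX163
PANX164
PANX165
PANX166
PANX167
PANX168
PANX169
PANX170
PANX171
PANX172
PANX173
PANX174
PANX175
PANX176
PANX177
PANX178
PANX179
PANX180
PANX181
PANX182
PANX183
PANX184
PANX185
PANX186
PANX187
PANX188
PANX189
PANX190
PANX191
PANX192
PANX193
PANX194
PANX195
PANX196
PANX197
PANX198
PANX199
PANX200
PANX201
PANX202
PANX203
PANX204
PANX205
PANX206
PANX207
PANX208
PANX209
PANX210
PANX211
PANX212
PANX213
PANX214
PANX215
PANX216
PANX217
PANX218
PANX219
PANX220
PANX221
PANX222
PANX223
PANX224
PANX225
PANX226
PANX227
PANX228
PANX229
PANX230
PANX231
PANX232
PANX233
PANX234
PANX235
PANX236
PANX237
PANX238
PANX239
PANX240
PANX241
PANX242
PANX243
PANX244
PANX245
PANX246
PANX247
PANX248
PANX249
PANX250
PANX251
PANX252
PANX253
PANX254
PANX255
PANX256
PANX257
PANX258
PANX259
PANX260
PANX261
PANX262
PANX263
PANX264
PANX265
PANX266
PANX267
PANX268
PANX269
PANX270
PANX271
PANX272
PANX273
PANX274
PANX275
PANX276
PANX277
PANX278
PANX279
PANX280
PANX281
PANX282
PANX283
PANX284
PANX285
PANX286
PANX287
PANX288
PANX289
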