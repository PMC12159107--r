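# source=neutron
# fraction_d2o=0
# concentration=1
# pressure=0.1013
# temperature=20
# absolute_scale=true
# label=synthetic NCP, 0% D2O
# sigma_imputed=false
# units=cm^-1
0.009 0.11444591 0.0040715277
0.011445378 0.11529084 0.0040380683
0.013890756 0.10708075 0.0039972323
0.016336134 0.10682525 0.0039494134
0.018781513 0.10292644 0.0038950734
0.021226891 0.101554 0.003834738
0.023672269 0.094385189 0.0037689916
0.026117647 0.086370018 0.0036984722
0.028563025 0.084647132 0.0036238646
0.031008403 0.074941974 0.0035458938
0.033453782 0.071908515 0.0034653168
0.03589916 0.06175219 0.0033829141
0.038344538 0.06357655 0.0032994802
0.040789916 0.048697518 0.003215813
0.043235294 0.0473968 0.0031327026
0.045680672 0.042491211 0.003050919
0.04812605 0.035755454 0.0029711992
0.050571429 0.033935087 0.0028942335
0.053016807 0.027254427 0.0028206522
0.055462185 0.020040257 0.0027510121
0.057907563 0.021694545 0.002685784
0.060352941 0.020784323 0.0026253421
0.062798319 0.015358037 0.0025699559
0.065243697 0.009804432 0.0025197857
0.067689076 0.013092767 0.0024748813
0.070134454 0.005866738 0.0024351858
0.072579832 0.0087472949 0.0024005432
0.07502521 0.0059197999 0.0023707103
0.077470588 0.0061035082 0.0023453712
0.079915966 0.0051746843 0.0023241545
0.082361345 0.0052707009 0.0023066511
0.084806723 0.0031923751 0.0022924319
0.087252101 0.0043315276 0.0022810638
0.089697479 -0.003084852 0.0022721247
0.092142857 0.0040072326 0.0022652143
0.094588235 -0.00056268348 0.0022599641
0.097033613 0.0012762555 0.0022560425
0.099478992 0.0028409181 0.002253159
0.10192437 -0.0030899411 0.0022510653
0.10436975 0.0016137999 0.0022495543
0.10681513 0.001640425 0.0022484581
0.1092605 0.0022232605 0.0022476447
0.11170588 -0.0047208476 0.0022470139
0.11415126 -0.00056497542 0.0022464928
0.11659664 -0.0020361602 0.0022460313
0.11904202 0.0013318958 0.0022455975
0.12148739 0.0016853984 0.0022451735
0.12393277 -0.0011958792 0.0022447517
0.12637815 -0.00028082555 0.0022443314
0.12882353 -0.0029781073 0.002243916
0.13126891 -0.002247195 0.002243511
0.13371429 -0.0002997061 0.0022431221
0.13615966 0.0015955535 0.0022427542
0.13860504 -0.0028483693 0.0022424108
0.14105042 0.0019492841 0.0022420934
0.1434958 -0.0020998007 0.0022418018
0.14594118 0.00061545703 0.0022415341
0.14838655 0.0027659086 0.0022412872
0.15083193 0.0028537479 0.0022410571
0.15327731 -0.00074515663 0.0022408395
0.15572269 -0.00037788896 0.0022406301
0.15816807 -0.0029665873 0.002240425
0.16061345 -0.0012508854 0.0022402209
0.16305882 0.000428602 0.0022400155
0.1655042 0.0011139195 0.0022398073
0.16794958 0.001024239 0.0022395956
0.17039496 -0.0013919892 0.0022393806
0.17284034 0.00047192431 0.002239163
0.17528571 -3.7347804e-07 0.002238944
0.17773109 -4.8610052e-05 0.0022387251
0.18017647 0.0034890855 0.0022385077
0.18262185 0.0037254674 0.0022382934
0.18506723 0.0026710312 0.0022380833
0.18751261 -9.2674498e-05 0.0022378783
0.18995798 -0.0039981129 0.0022376791
0.19240336 -0.002257826 0.0022374861
0.19484874 0.00073185493 0.0022372995
0.19729412 -0.0028118949 0.0022371192
0.1997395 0.00034870185 0.0022369453
0.20218487 -8.2279293e-05 0.0022367781
0.20463025 0.0041671313 0.0022366177
0.20707563 0.0025039675 0.0022364647
0.20952101 -0.0011323186 0.0022363202
0.21196639 -0.0012109723 0.0022361853
0.21441176 -0.0038662756 0.0022360615
0.21685714 0.0010473279 0.0022359507
0.21930252 2.5040754e-06 0.0022358546
0.2217479 0.0030008356 0.0022357752
0.22419328 0.0016030524 0.0022357142
0.22663866 0.003453328 0.002235673
0.22908403 0.0029447127 0.0022356525
0.23152941 -9.5145522e-05 0.0022356534
0.23397479 -0.00082467262 0.0022356752
0.23642017 -0.0016257744 0.0022357171
0.23886555 0.00061753566 0.0022357776
0.24131092 -0.0017770642 0.0022358541
0.2437563 -0.0010003323 0.0022359439
0.24620168 0.0030510845 0.0022360434
0.24864706 0.001116004 0.002236149
0.25109244 -0.0018127597 0.0022362567
0.25353782 0.00061267484 0.0022363627
0.25598319 -0.0013067628 0.0022364635
0.25842857 0.0047934825 0.0022365559
0.26087395 0.0026484781 0.0022366373
0.26331933 0.0016988266 0.0022367061
0.26576471 -0.00048458053 0.0022367613
0.26821008 0.00022920504 0.002236803
0.27065546 -0.0048504821 0.0022368321
0.27310084 -0.0010087937 0.0022368503
0.27554622 0.0038066898 0.0022368602
0.2779916 -0.0012347187 0.0022368649
0.28043697 -6.8776332e-05 0.0022368679
0.28288235 -0.00031512909 0.0022368732
0.28532773 0.0036205491 0.0022368844
0.28777311 0.0017568506 0.0022369051
0.29021849 -0.0016871486 0.0022369385
0.29266387 -0.0013697165 0.0022369871
0.29510924 -0.0018133415 0.0022370525
0.29755462 -0.0012746359 0.0022371357
0.3 0.0022471985 0.0022372366
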