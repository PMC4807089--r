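>synref_rdrp_ss_1 synthetic reference protein (generated stand-in)
PFIRSGASVVLYVVSFDIQMVRETDIILGDGDQRVAIDRIQKRPKILASGEVDTDVFTIT
LIKLTQAKTAHTDQMITSTDCTYSVALALAMIDVETYHDSKLGYYLPASTKFALITLGQG
LERSNKYSKVDDACGCLVSVLYGRIASQLVLTPELAANLHTAYFFHVVINKPNHLSPVKS
LPIRSQMQIQLPDAGPVSFRNVPVRYHIVPANGGRQWVSGYASVSTKHVGAQCFIHTLPN
DYSDFDASQHALGARKTHKRYFQVDNRGQYTRSITGLVCQVRCFFQGSRLSGWLLTQSLD
SGLTCSMVFKMGRLFRIRGNSKGLIDGCMLLAYSGDDSLIVDNAYLRLVVIEAIALSDVN
CDTYHTEMMSAKDPLKRWVKAGVAEDKPDASNGPFMRIRANTHVTTSLESFLRWETIEAG
VHFAFAPIELVAMKAAGAVLKGAQLFIFTVKAGARVTAVDEEDGDFRLGPEHDDQNVIEN
QRKGAIWLSDGILAPTEYDARDVLGLVSFIAVNFNGRCLKQEYDLGGPTDLEAEALEKIN
SLD
>synref_rdrp_ss_2 synthetic reference protein (generated stand-in)
GFIGSFKFFALYLMSFAIQMDRGTDIILRDGDRGVAIDWIYKRPKILATGEVWTAHFRRT
LIRVVCAKTAHYDQMWTKSSCNLSVALADAQNVVETYHDHHEGYSLPRTTKFALITLHQG
LEHSNKYNKVDDAQGCLVAVLYGGNPSNLVLTRRSAFNYHTAYTFHPVEELCNQLVCVKS
LPIRQRMWFQLPCCYPVSWRNVPYDATDVPAKGGSQCFSGTIKWSFKHRQAQDFRHCWDN
DYSDFDASQHALGSRKKHKRYFQWDNRQGYTRSMTGLVCLVAMTFQGSRLSGWLLTQSLA
SGHMCSMLFKMDNRMRIRWTMKGLILGMVLLAYSGDDSLIGFLAYLRLVLEMPMALSWVD
CDTYHVEMPSAKDPLKRWVKAEVAQCVMSARLGPVMRIRYNTSVTTSLESFLRPETIPIG
VHFAFQHIELVAEMARGIGLKGAQLFIQTMHRGARVTAVVEYTQDFRLGPEVTDQKAYEN
QWKQAIWLSDCMLAVTEADSLDVLELCRFSAHPFQWRCLKQWYDLLYPTDLEAKALIKAN
SDD
>synref_rdrp_ss_3 synthetic reference protein (generated stand-in)
PFIVSGASVVGYPVNQDIQMVRESPIFLGDGDCDNAIMCIQKRPKVCGSGEYDTCVFAQT
LIALTQAKIAHTYGMITSQFCTYKYAWALHYIMQGIYHDSKLGHCVPTHTKFLFITGVQG
YGRSDKYPKVKDIEGCGVSVLWDTIASQLVLTPEWALFEHGAYFFHDVNWATNRSAPEMP
LPARSQRQIPAPDHIPVSFRVVYERYFIVPANGGRQWVQGYASVSTKHVGAQCLFVYHPN
DYSDFDASQHALGARKDHKMYFCDDNRGQHTDKITGMDCQDTCYFQGSRLSGWLLTQSLD
SGLHCSMDFKMERLSRIRGRYKGDIEGVCFLAYSGDDSLIADNAPLRYVVEGAIHLPRSN
CPQRHTFMMFAKDPLKRWVKNGVEEGKIRASNGYFILHTAVDHDTTSLESFLRWMTGEQN
VHFAFGPKELEAMCNQGAELKGAQWMIFTDKLGERVGVQDEEDGPQALLREEQDQNVIEN
QRKGAIWLNEGIDAKTQYQYWDVLGLVSKICVNFNGRCQWQGYDLKGPTDWEAEIDNKIY
SHD
>synref_maturation_1 synthetic reference protein (generated stand-in)
SKVFPDHFHVFWPEDPGSLQAFGVRTRIVNRVEKASGMVELAAWLRYAALRYVGAAQSSG
WNDSRLSPTQFAQHGIGRTFDEAVEGGIQVENEQLVVGSTFAIAAAATLDFLLIAEANHS
VAKGFDTLPLIGNTRGGCLKRWAVDEVDPQDDMIFRIFWGVFVRFEGTSAKSVSSLNPGA
YSHQGRSLFRLGAWALVLTGPDKVINTIRTELLGETEAYEMKQPVITADPALRDLISGFR
AVENKTIIESSVEGANKLAFAVNTLVNPDVAQFNQDALGYNRERKMDEFINCICVDPLVL
FKPLTAESWQRYDLASGHGGTHTSPKSYLIKSCHPKRHIEIPGSRVESVVRYINTQQASG
RQAAFYVETDAATTFIQGPESEQAENVGVREMESLQYLEGKGNEGLAKNRSPEEKVLGQN
CYT
>synref_maturation_2 synthetic reference protein (generated stand-in)
AKCEPDHFEVGPPEDPGSPGAFPMRTRIANRPEKASQIMALGQWGIYYACRPMGAGWASG
WNDSRLSPTQFAQHGIGREFHASCEGGICVETEQLVVGATRAWATAATLKHLLSNEMNHS
VYKGCDTLPLIGATRGETLVRSAVVEEIPQKDMIFRNFRGVGVRMWPTSVASRGCHNVGH
YSNAGHSLWRLGAIDTVLTDPDQWINTGSTELIGETEAVEMKQPVETHDHALRDLIRGFC
AVCGNVIIESSGFGTNLLACAVFTLVHPDKVDDFVDAEYWPREYKVGEFINCIKVVPLVT
FKPLTAESWQRYDLASGHGGTMTSKWSYLAKSCHPKEHICVPFWVVESVVRCGCPCQHRG
RQAAGIVETDADTTPIWGWEVYQCGFAIVR
>synref_maturation_3 synthetic reference protein (generated stand-in)
SKDFPYHCHVFNAEDPGDLQASGQRSRIVNRVNKQSGRICTAKFLMYADERYTGAADGST
WNDSRLSPTQFAQHGIGRTFDSVMDGGIQVTNEQLVVGSWFMIAAAATLSFLLPADANVS
VAAGADTLPLIGVTRGGPYKANAVDESDPQDDMTFPIFWGVFIRFEGTSAWSVSSLNINP
YSCQLRSLNRLGANDLDLTGYDVYINTIAKGLLGKPMAYEPAQTFITTLPALRDLYSRDR
DAFNYTWISSSAEGAHKQAFPVMTLDNPDIKSFNQGALGYGRERKTDEFYIEICVALLCL
FKPLTAESWQRYDLASGHGGCHTWCKSYRIRMCRNKRHICIGGDAVESVVRRANQQFDCG
RFPAFYLWTNKATDFTQIPTSEVAEDVVVTLWENLQSCENKPNEFLAKNRSCEEFVTGLN
CYTLRLTLYYIPLGFRRLSKDGTMVIKLSCLITILYK
>synref_coat_1 synthetic reference protein (generated stand-in)
LGGIRTVGIPNRQAFTFAAAIELRDGQSVNLAEFTKGSIDVAMATKADNSKLRATTLFRK
ENYVSEFLGSQVRAVAHGIANARVLWAPSNRQLDITKALAGWTDIFSGVLKHELALEVQY
EAVTASLDT
>synref_coat_2 synthetic reference protein (generated stand-in)
CGGICTVGMRYSYLTTQAAAPEERDGQSVNLAEFTKGSIHLDQAQKADNSRLRHTTYTRK
ENQHSVFFGSFPRAVAHGIAPARVLWAPSNRQLDITKALTVQTSIPSGVVKLEFAPHYWF
FAVTAGLRT
>synref_coat_3 synthetic reference protein (generated stand-in)
LGGIRTHGYPHRSASQKAAADEYRVGQSVNLAEFTKGSIRYAMATKANHNDLRTTDHFNK
SYYVSTFLGMQVGAANIGFRLNLVLWAPSNRQLDITKALHHWTNNPCHVLKHRDALEMGY
EPVTAEPDT
>synref_lysin_1 synthetic reference protein (generated stand-in)
ENRQVPADGLSKQRIIMLQLAKLVVLSRNLTTDVEQFTPDTSTGGTKALHNYVCDVRLGG
FLYEVTQHSVLWFWEDYKLVQYLQTEVENVANLFPIQKATGEDSCTLCAVGVLLITMRVA
>synref_rdrp_ds_1 synthetic reference protein (generated stand-in)
CSVCLKKCFEHKAKEEVCSAINSFVVEFHGILLRLLQQQIKSQDDLFVTKDGKFIMVLFL
VATAVKKGLFMLPDGAPERLYFSRLDLTDGNRQCSGKEKRENHNTDEAALGIPETHESFQ
KRISLKGGYVDIGAYLDFSNAKLLRGSEPTAWIFILKLLGTEPFLVYATSQLMNLNDVKK
HRHEVIAVWRVGPCKPRIKGHVGFNRGENHKDVLLENVNKLFYRQNTDVGAQMAKGKTPP
AIPNEFVLSTDFSAWDQTAHSGRDDKILYVRAAKPFTVNRGFRTAAQFMKTVADLDLIGT
AFILGSDSYWDPYQDFDLMEPSVLNFGSTVMLASGDDGLISRNTRNLERAVNKLHTCSTH
NEPEDNKPAGFLIAKLVSMEAFKLRTLRLGIGFRFDCALEFTVVQYTSEVFKRAYIISRS
PGYVQRADSNEVPSFDQDEDPMGLNNLTILGTTIREVQGRSLQPSYAAASTIIAVRNPES
KQGLDPIRGVTESKPVSGIVAQIAKELQGGGFLAIAGEESQGYAESKQKTEVNLKTELVA
ILVLAKVEQNNTFASPWKKPQSGKIIKDGKTLAHPVVCMYRTTDMFQVTPKSETNIVFRL
>synref_rdrp_ds_2 synthetic reference protein (generated stand-in)
CSRCRLQCCENKCKMEVHSARLSFVVEFHGILLYKTQQVIKSDDDLFVTKDGYDIMVLYL
LSTEVKKGMYMLPPGAHERLYFSRLDLSLGQRHCSPKEKIENMNLCEASLGIDEKQSFGI
LRVSLKSHGVSIETYLLFRNAKLHDGSPCTAPIKFLKMLGTEEFCGHRTSQCMCLWCVKC
HRMEIDWGWRVGPCLCRRKGWVGIVWKENRKDQLLENMNKLFYLQCTDSGACMVKGCLPA
AIWVEFVHNWDFSAWDQTAHSGGYDKCLYYRADKPFTQNRIAKLFAQFMKTCFYLLEIGR
RFELGVDVYSKPYQQFFLMRVDVLNKKSWFMLASGDDGLISRNTYNLNRTVNMLSTQSPY
NEPEQNGPANFLAAKCVSMGAFKLKNLSLKQGERRDGALSFTVKYYGSEVAKANTIISVS
PSFVQRAYGNEVIFVDQYEMPMGLNNSTILGTTPREVQTRSYQSSYAATDTCIAVRNNMS
KQRDDTIRSVEEIKHVSNIFAPIADMLQGGGDHAIQLHESLGVAEMKQKTEVSLKTNLVA
WLALAKVEQNNTHWECPFIPRSGKECQPGTILWHIVVSMVRTTDMFSTCPCSDTSIVFRC
>synref_ntpase_1 synthetic reference protein (generated stand-in)
IYGELEIYLISLAFVEIYSAPGSSNQLNEEMLLVVNHSCTWMLAERIYPSLGFGKGQESC
IQGLVIKIGINQKLTAQKVFRPCNRIPTTVSSLQRLPGKNTYQLHSAVIRVGICVEGLNC
IYIQRAAIQILECGRGATGETAGGSGNDQAGAYLPVSIILISRTETQRRQPKAKRFNLQK
HWAVIFVPGKPKSLRWEAIEDLVYVYAKSVEGGVQRVGVLLDTQQFHTIASRFGAVLVYE
MKWELKGLVDDKEDAYGLSDGISLLMGNKMKISEPNQPPEGHDVNLVTSVGAAVQSCTGE
ILVLRRERGDESLCPKLATFFILVKKNIFPHIDHPAVDNESSTVIVLLFW
>synref_peptidoglycan_hydrolase_1 synthetic reference protein (generated stand-in)
ASDHPQEREDGSNTLQNMSYMGEVQSLPDKRMVETGSKAIRRKKTNQYESIPACRRLLTL
SAKSFGLVRTFRLSIVLAELLDGTRRTLTLGRFGTQGTQRPTLYEKSDFRRRADALKMPI
ILEILKPLEERTPQGGVIDTLSDIEAFEKRVPTSGFGNRFEVERWSRFINVTGEAALCFG
FPSRNPGQVSMKGGRAAVIRLKLAGAMRHAFNGVNLVRMKSYTEWVGGTDLTEEGNGAYV
PALNRSARSV
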