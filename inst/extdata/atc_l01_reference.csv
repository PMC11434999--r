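drug,atc_code
bendamustine,L01AA09
busulfan,L01AB01
carmustine,L01AD01
chlorambucil,L01AA02
cyclophosphamide,L01AA01
dacarbazine,L01AX04
ifosfamide,L01AA06
lomustine,L01AD02
melphalan,L01AA03
temozolomide,L01AX03
azacitidine,L01BC07
capecitabine,L01BC06
cladribine,L01BB04
cytarabine,L01BC01
decitabine,L01BC08
fludarabine,L01BB05
fluorouracil,L01BC02
gemcitabine,L01BC05
mercaptopurine,L01BB02
methotrexate,L01BA01
pemetrexed,L01BA04
cabazitaxel,L01CD04
docetaxel,L01CD02
etoposide,L01CB01
irinotecan,L01CE02
lurbinectedin,L01CX02
paclitaxel,L01CD01
topotecan,L01CE01
trabectedin,L01CX01
vinblastine,L01CA01
vincristine,L01CA02
vinorelbine,L01CA04
bleomycin,L01DC01
dactinomycin,L01DA01
daunorubicin,L01DB02
doxorubicin,L01DB01
epirubicin,L01DB03
idarubicin,L01DB06
mitomycin,L01DC03
valrubicin,L01DB09
abemaciclib,L01EF03
afatinib,L01EB03
alectinib,L01ED03
alpelisib,L01EM03
avapritinib,L01EX18
axitinib,L01EK01
bosutinib,L01EA04
cabozantinib,L01EX07
crizotinib,L01ED01
dabrafenib,L01EC02
dasatinib,L01EA02
entrectinib,L01EX14
erdafitinib,L01EN01
erlotinib,L01EB02
everolimus,L01EG02
fedratinib,L01EJ02
gefitinib,L01EB01
imatinib,L01EA01
lenvatinib,L01EX08
neratinib,L01EH02
nilotinib,L01EA03
nintedanib,L01EX09
osimertinib,L01EB04
palbociclib,L01EF01
pazopanib,L01EX03
pexidartinib,L01EX15
pralsetinib,L01EX23
regorafenib,L01EX05
ribociclib,L01EF02
ruxolitinib,L01EJ01
sorafenib,L01EX02
sunitinib,L01EX01
trametinib,L01EE01
tucatinib,L01EH03
vemurafenib,L01EC01
atezolizumab,L01FF05
bevacizumab,L01FG01
cetuximab,L01FE01
daratumumab,L01FC01
enfortumab vedotin,L01FX13
ipilimumab,L01FX04
nivolumab,L01FF01
panitumumab,L01FE02
pembrolizumab,L01FF02
pertuzumab,L01FD02
rituximab,L01FA01
trastuzumab,L01FD01
trastuzumab deruxtecan,L01FD04
bortezomib,L01XG01
carboplatin,L01XA02
carfilzomib,L01XG02
cisplatin,L01XA01
enasidenib,L01XX59
glasdegib,L01XJ03
ixazomib,L01XG03
mitotane,L01XX23
niraparib,L01XK02
olaparib,L01XK01
oxaliplatin,L01XA03
romidepsin,L01XH02
rucaparib,L01XK03
selinexor,L01XX66
sonidegib,L01XJ02
tazemetostat,L01XX72
tretinoin,L01XF01
venetoclax,L01XX52
vismodegib,L01XJ01
vorinostat,L01XH01
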