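binomen,genus,family,synonyms,common_names,is_mivs,regions
Bitis arietans,Bitis,Viperidae,,puff adder,TRUE,Africa
Bitis gabonica,Bitis,Viperidae,,Gaboon viper,TRUE,Africa
Echis ocellatus,Echis,Viperidae,,West African carpet viper,TRUE,Africa
Crotalus scutulatus,Crotalus,Viperidae,Caudisona scutulata,Mojave rattlesnake,TRUE,NorthAmerica
Crotalus oreganus,Crotalus,Viperidae,,Pacific rattlesnake,TRUE,NorthAmerica
Agkistrodon contortrix,Agkistrodon,Viperidae,,copperhead,TRUE,NorthAmerica
Naja naja,Naja,Elapidae,,Indian cobra|spectacled cobra,TRUE,Asia
Dendroaspis polylepis,Dendroaspis,Elapidae,,black mamba,TRUE,Africa
Micrurus diastema,Micrurus,Elapidae,,variable coralsnake,TRUE,NorthAmerica
Micrurus fulvius,Micrurus,Elapidae,,eastern coralsnake,TRUE,NorthAmerica
Lampropeltis getula,Lampropeltis,Colubridae,Lampropeltis getulus,eastern kingsnake,FALSE,NorthAmerica
Pliocercus elapoides,Pliocercus,Colubridae,,variegated false coralsnake,FALSE,NorthAmerica
Pantherophis guttatus,Pantherophis,Colubridae,Elaphe guttata,corn snake,FALSE,NorthAmerica
Thelotornis capensis,Thelotornis,Colubridae,,southern twig snake,TRUE,Africa
Dispholidus typus,Dispholidus,Colubridae,,boomslang,TRUE,Africa
Boa constrictor,Boa,Boidae,Constrictor constrictor,boa constrictor,FALSE,SouthAmerica
Charina bottae,Charina,Boidae,,rubber boa,FALSE,NorthAmerica
Python sebae,Python,Pythonidae,,African rock python,FALSE,Africa
Python regius,Python,Pythonidae,,ball python,FALSE,Africa
Atractaspis bibronii,Atractaspis,Lamprophiidae,,Bibron's stiletto snake,TRUE,Africa
Psammophis sibilans,Psammophis,Lamprophiidae,,hissing sand snake,FALSE,Africa
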