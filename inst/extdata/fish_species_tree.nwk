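(tetrapods:416,(gar:360,((zebrafish:150,cavefish:150)Otophysa:81,(cod:190,(fugu:150,(stickleback:130,(tilapia:110,(medaka:90,(platyfish:60,molly:60)Poeciliinae:30)Atherinomorphae:20)Ovalentaria:20)Percomorpha:20)Acanthomorpha:40)Euteleostei:41)Teleostei:129)Actinopterygii:56)Root;
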