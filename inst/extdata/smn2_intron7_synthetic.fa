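>SMN2_ex7_intron7_synthetic offset=-23
GCUCACAUUCCUUAAAUUAAGGAGUAAGUCUGCCAGCAUUAUGAAAGUAAUACAUACUUUCGUAACAAAUCAAUUGUCUGAGUAACAUAAAAUGGCGGGAUUCUUGAAGCACAAAAUACAUGGAGGUCCUAGAAUCUACCGCGUCACAGAAUACCAAUCAUUGCAAAUAAAUACUUUUAGUUAACGGAACAGUUACUUAACAUUUCCCCGACUAUAUAGUAUUGUUUCUCAUGAAAACAUGGAUAACGACUGUAUUUCAAUAGAAUACUUAACGGAAUAGAAUUCAUUCAUACUAACAUGUUACGCAGACAAGCAGACUUUUUAUUUCAUAACCUUAUUUACCAAUCUACUAUAUGGCGGAAUUACUUCUAAUGAAACCGCGUAUCUAGGAUAUUUGUACAUAGUCCUUAAAGCUACUAACUUGAGCGGUAGUCCUUAUAAAUAUCAUCAUUCGACCGCGGAAAACA
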