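# System-role matrix (SR): which of the seven system tasks (a)-(g) each of
# the four system roles may perform.  Task semantics (reconstruction, see
# the methods vignette):
#   a = manage user accounts
#   b = enter/modify own workflow data
#   c = search/view data
#   d = generate reports
#   e = export data
#   f = manage lab-wide resources (codes, protocols, storage, any project)
#   g = manage own account/password
# Format: role: task [task ...]
user_administrator: a g
lab_manager: c d e f g
scientist: b c d e g
visitor: c d g
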