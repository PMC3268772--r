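# Database-role matrix (DR): data actions granted to each of the five
# database roles.  write includes read; full_right is the union of all.
# Format: role: action [action ...]
read: read
write: read write
delete: read write delete
manage_user: manage_user
full_right: read write delete manage_user
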